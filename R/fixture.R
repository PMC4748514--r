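# The worked SideRaises example: a weight-lifting game (raise hand weights
# sideways to shoulder height) recorded through a Kinect and presented on a
# smart TV, together with one recorded session of it from the living-lab
# deployment.

FFA_RES <- "http://www.fitforall.gr/resources/"
DBPEDIA_KINECT <- "http://dbpedia.org/resource/Kinect"
QUDT_SECOND <- "http://qudt.org/vocab/unit#SecondTime"

#' The SideRaises worked example
#'
#' Returns the SideRaises game description and the published session of it:
#' three metrics (success, reaction time, goal time), a Kinect controller
#' linked to its DBpedia resource, a smart-TV presentation hardware, and an
#' exercise involving the deltoid, infraspinatus, teres minor, teres major
#' and latissimus dorsi. The session carries the published per-iteration
#' Success values (true, true, false, true, false, true) for player
#' `player162` at the Medical Physics Laboratory site.
#'
#' The published excerpt elides the reaction-time and goal-time value
#' sequences; this fixture fills them with fixed synthetic values (seconds,
#' six iterations) so the session is structurally complete. The assignment
#' of muscles to OPE individuals versus NCIt subclasses is likewise a
#' package assumption (the source names the muscles but not their
#' provenance split).
#'
#' @return A list with elements `game` (a `GameDescription`) and `session`
#'   (a `SessionRecord`). Deterministic: two calls are structurally equal.
#' @examples
#' fx <- sideraises_fixture()
#' length(fx$game$metrics)     # 3
#' fx$session$observations[[1]]$values
#' @export
sideraises_fixture <- function() {
  concept_time <- paste0(NS_CONCEPT, "Time")
  metrics <- list(
    define_metric("Success", "success"),
    define_metric("ReactionTime", "reaction time",
                  concept = concept_time, unit = QUDT_SECOND),
    define_metric("GoalTime", "goal time",
                  concept = concept_time, unit = QUDT_SECOND)
  )
  exercise <- exercise_definition(
    iri = paste0(FFA_RES, "SideRaisesExercise"),
    label = "side raises",
    muscles = list(
      muscle_ref(paste0(NS_OPE, "Deltoid"), "OPE"),
      muscle_ref(paste0(NS_OPE, "Latissimus_dorsi"), "OPE"),
      muscle_ref(paste0(NS_NCI, "Infraspinatus"), "NCIt-subclass"),
      muscle_ref(paste0(NS_NCI, "Teres_Minor"), "NCIt-subclass"),
      muscle_ref(paste0(NS_NCI, "Teres_Major"), "NCIt-subclass")
    ),
    equipment = "hand weights"
  )
  game <- game_description(
    iri = paste0(FFA_RES, "SideRaisesGame"),
    label = "SideRaises",
    metrics = metrics,
    controllers = list(
      controller_definition("Kinect", "Kinect", same_as = DBPEDIA_KINECT)
    ),
    presentation_hardware = list(
      list(iri = paste0(FFA_RES, "SmartTV"), label = "smart TV")
    ),
    exercise = exercise,
    goals = list(
      list(kind = "game_goal",
           text = "raise both arms to shoulder height in time"),
      list(kind = "exercise_goal",
           text = "proper execution of the side-raise repetitions")
    )
  )
  stamp <- "2014-09-22T18:09:39+02:00"
  session <- session_record(
    session_id = "SideRaisesGameSession",
    game = game$iri,
    player = paste0(FFA_RES, "player162"),
    site = paste0(FFA_RES, "MedicalPhysicsLaboratoryAuth"),
    start = stamp,
    end = stamp,
    observations = list(
      metric_observation(paste0(NS_METRIC, "Success"),
                         c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)),
      # reaction-time / goal-time sequences are synthetic (not published)
      metric_observation(paste0(NS_METRIC, "ReactionTime"),
                         c(1.2, 1.5, 2.1, 1.4, 2.4, 1.3),
                         unit = QUDT_SECOND),
      metric_observation(paste0(NS_METRIC, "GoalTime"),
                         c(3.8, 4.1, 5.2, 4.0, 5.6, 4.2),
                         unit = QUDT_SECOND)
    )
  )
  list(game = game, session = session)
}
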