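# The SideRaises game as a loadable game-description document
# (same content as sideraises_fixture()$game).
iri: http://www.fitforall.gr/resources/SideRaisesGame
label: SideRaises
metrics:
- local_name: Success
  label: success
- local_name: ReactionTime
  label: reaction time
  concept: http://purl.org/net/exergame/concept#Time
  unit: http://qudt.org/vocab/unit#SecondTime
- local_name: GoalTime
  label: goal time
  concept: http://purl.org/net/exergame/concept#Time
  unit: http://qudt.org/vocab/unit#SecondTime
controllers:
- local_name: Kinect
  label: Kinect
  same_as: http://dbpedia.org/resource/Kinect
presentation_hardware:
- iri: http://www.fitforall.gr/resources/SmartTV
  label: smart TV
exercise:
  iri: http://www.fitforall.gr/resources/SideRaisesExercise
  label: side raises
  muscles:
  - iri: http://www.semanticweb.org/ontologies/2013/2/OPE.owl#Deltoid
    source: OPE
  - iri: http://www.semanticweb.org/ontologies/2013/2/OPE.owl#Latissimus_dorsi
    source: OPE
  - iri: http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Infraspinatus
    source: NCIt-subclass
  - iri: http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Teres_Minor
    source: NCIt-subclass
  - iri: http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#Teres_Major
    source: NCIt-subclass
  equipment:
  - hand weights
goals:
- kind: game_goal
  text: raise both arms to shoulder height in time
- kind: exercise_goal
  text: proper execution of the side-raise repetitions
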