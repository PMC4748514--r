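---
title: "Exergame telemetry as linked open data: model, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exergame telemetry as linked open data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exergraph)
```

## The data model and its assumptions

An exergame session is one continuous play period of one player on one
game: it starts with the game and ends when the game ends or stops. The
ontology attaches to each session its player, game, site, start and end
timestamps, and a result object. Because RDF properties are binary, the
result's n-ary association (result × metric × unit × value) is reified
through an auxiliary `exergame:MetricRelation` node per metric;
per-iteration values are ordered with an `rdf:Seq` container whose
membership properties `rdf:_1..rdf:_n` must be contiguous from 1. A
metric observed for a single iteration attaches its value as a plain
typed literal instead — the package reads *both* encodings back (and the
strict validation profile flags a length-1 sequence as a degenerate
encoding).

Modelling assumptions made where the published ontology description is
silent:

* **Linkage properties.** The properties attaching a game to its
  metrics, controllers, presentation hardware and exercise, and a metric
  relation to its unit, are never printed in the ontology's public
  description. This package mints `exergame:{gameMetric, gameController,
  presentationHardware, gameExercise, metricUnit}` (plus exercise
  annotations `involvesMuscle`, `equipment`, `healthBenefit`, and goal
  annotations `gameGoal`, `exerciseGoal`). They live in the registry
  returned by `default_terms()` and can be remapped wholesale if an
  authoritative vocabulary becomes available.
* **Goals** are kept as string annotations (`game_goal` /
  `exercise_goal`), not typed individuals: no class IRIs for goal kinds
  are published.
* **Players** are modelled by the `exergame:Player` class; whether it is
  declared a subclass of `foaf:Person` is left to the ontology itself —
  the package only ever emits opaque player IRIs, in line with the
  deployment's anonymization rule. Optional demographics (age, gender)
  exist on `PlayerRecord` purely as cohort attributes for the simulator
  and are never serialized.
* **Muscle provenance.** The SideRaises example names five muscles but
  not which come from the physical-exercise ontology (OPE) versus the
  NCI Thesaurus. The fixture assigns deltoid and latissimus dorsi to OPE
  and declares infraspinatus, teres minor and teres major as subclasses
  of `nci:Muscle`; this split is an assumption and only affects the
  fixture, not the machinery.
* **Normalizations.** The published prefix block and one metric IRI
  print `purl.com` where every other mention uses `purl.org`; parsers
  normalize to `purl.org`. Printed timestamps show a mangled offset
  (`2014-09-22T18:09:39 02:00`), interpreted as `+02:00`; all emission is
  strict ISO-8601 with an explicit offset. Boolean values print as
  TRUE/FALSE in the published table; the package emits the XSD lexicals
  `true`/`false` and accepts the upper-case forms on input.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_players`, `n_male` | 14, 3 | persons | pilot cohort (3 male, 11 female) |
| `age_mean`, `age_sd` | 73.4, 5 | years | cohort mean is published; spread is a package choice, clamped to [60, 95] |
| `visits_per_player` | 6 | days | pilot protocol |
| `games_per_visit` | 7 | games | pilot protocol; the catalog ships 7 games, SideRaises first |
| `iterations_range` | (6, 10) | iterations | the worked session shows 6 iterations; a small spread above it keeps sequences non-trivial |
| Success model | Bernoulli(0.7) | — | no distributions are published; 0.7 reflects a mostly-successful elderly cohort |
| ReactionTime model | lognormal(log 1.5, 0.4) | s | strictly positive, right-skewed reaction times around 1.5 s |
| GoalTime model | normal(4, 1) truncated at 0 | s | a paced repetition of a few seconds; truncation guarantees positivity (rejection sampling) |
| `session_gap_minutes` | (2, 8) | min | rest between games within a visit |
| `utc_offset_minutes` | 120 | min | the deployment's local offset (+02:00) |
| `seed` | 42 | — | every draw goes through one seeded RNG; identical seeds give byte-identical canonical graphs |

All of these are overridable programmatically or through the YAML
configuration read by `pilot_config_from_yaml()`.

## What the simulator emulates — and what it does not

The generator reproduces the *structural* shape of the living-lab
deployment: cohort size and composition, visit cadence, games per visit,
per-metric iteration sequences, ordered session times within a visit
day, one shared site, and everything stored in a single graph. Session
durations are derived from the drawn goal times plus overhead, which
lands total gaming time in the tens-of-hours order of the real pilot
without enforcing it.

It deliberately does **not** model behavioural realism: no learning or
fatigue effects across visits, no dropout, no between-player skill
structure (players are exchangeable draws), and no correlation between
success and reaction time within an iteration. Tests passing on
simulated pilots therefore demonstrate structural and algorithmic
correctness — emission, parsing, validation, querying, conversion — not
fidelity of any statistical analysis to real elderly players.
Iteration counts are drawn once per session and shared by all of a
game's metrics (they measure the same physical repetitions); the RDF
layer nevertheless accepts relations with differing sequence lengths.

## Numerical and representational choices

* **Literal lexicals.** One canonical lexical per value everywhere:
  booleans `true`/`false`; doubles formatted without scientific notation
  at up to 15 significant digits (continuous metric draws are rounded to
  3 decimals — millisecond resolution). The converter and the emitter
  share these helpers, which is what makes the CSV → RDF loop close
  bit-exactly after canonicalization.
* **Canonicalization.** Blank nodes are relabelled by iterative
  signature refinement (a node's signature is the sorted multiset of its
  incident triples with blank neighbours replaced by their previous
  signatures), with deterministic individualization when a signature
  class stays ambiguous; sorting uses C collation so output is
  byte-stable across locales. For the tree-shaped blank structures this
  ontology emits, refinement separates everything in a few rounds;
  adversarial regular graphs could in principle defeat the tie-break,
  which is acceptable for a telemetry format that never produces them.
* **Degenerate inputs.** Sessions with zero observations cannot be
  emitted; records reject reversed time ranges (equal start/end is legal
  — the published session prints identical stamps); sequence gaps and
  duplicate iterations are hard errors on read and violations on
  validation; empty graphs serialize to a prefix header and
  canonicalize to the empty string.
* **Validation profiles.** `compat` (default) enforces what every
  published session satisfies; `strict` adds unit presence, singleton
  sequences and site presence. The published excerpt itself shows no
  units, which is exactly why unit checking is strict-only.
* **SPARQL engine scope.** PREFIX, `SELECT [DISTINCT]` over variables or
  a single `COUNT(DISTINCT ?v)` aggregate, and basic graph patterns with
  `;`/`,`/`a`. That covers the dataset's canonical retrievals; FILTER,
  OPTIONAL, UNION and paths raise a parse error naming the construct.
  The per-iteration lookup ships both as a parameterized function
  (`metric_at_iteration()`, which also covers the direct-literal
  encoding at iteration 1) and as a query file
  (`inst/sparql/metric-at-iteration.rq`); the published query text is
  not reproduced verbatim anywhere, so this is a reconstruction of the
  described access path. A deliberately naive nested-scan oracle
  evaluates the same patterns independently, and the test suite requires
  engine/oracle agreement on seeded pilots.

## Problem sizes used by the test suite

Structural properties (round trips, cross-format isomorphism) run on 200
randomized sessions; engine/oracle equivalence on 100 seeded reduced
pilots (1 player × 1 visit × 2 games each); determinism and loop-closure
checks on reduced cohorts of 3 players × 2 visits × 2 games; the cohort
echo (14 distinct players, 7 games per visit, 6 visit dates per player)
runs on the full default pilot of 588 sessions. These sizes are the
package's choice of a thorough-but-quick default; all generators scale
by configuration.

## Known limitations

* No OWL reasoning or SKOS vocabulary service: the package treats the
  ontology as a structural contract, not an inference problem.
* The Turtle reader covers the subset the package and hand-written
  fixtures use (no `[]` property lists, collections, or `@base`), and
  unparseable bytes between tokens are skipped rather than rejected;
  structural errors still surface with line context.
* RDF/XML support is the `rdf:Description`-per-subject profile the
  writer produces (plus typed node elements on input); exotic RDF/XML
  abbreviations are out of scope.
* JSON-LD, TriG/named graphs, streaming parsers, HTTP endpoints and
  triplestore upload are out of scope; skolemization exists so uploads
  remain possible downstream.
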