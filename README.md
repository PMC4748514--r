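# exergraph

Exergames — serious games that pair gameplay with physical exercise — are
increasingly used as unobtrusive health-monitoring tools for elderly
players: every play session produces per-iteration *game metrics*
(success, reaction time, goal time) whose trends carry clinical signal.
For that telemetry to be comparable and publishable as open data, it needs
a shared semantic structure. `exergraph` implements, in R, the data model
of an OWL ontology for exergames (`http://purl.org/net/exergame/ns#`) and
the toolchain around it: build typed session records, emit and parse them
as RDF in exactly the ontology's structure, validate graphs (including the
anonymization rule for player nodes), query them with SPARQL, convert
legacy tabular logs, and simulate a full synthetic living-lab pilot.

## The model

RDF properties are binary, but a game result is an *n-ary* association —
result × metric × unit × value. The ontology resolves this with an
auxiliary node per metric:

```
_:session  a exergame:GameSession ;
    exergame:player <.../player162> ;        # opaque id, never a name
    exergame:game   <.../SideRaisesGame> ;
    exergame:site   <.../MedicalPhysicsLaboratoryAuth> ;
    exergame:startDateTime "2014-09-22T18:09:39+02:00"^^xsd:dateTime ;
    exergame:endDateTime   "2014-09-22T18:09:39+02:00"^^xsd:dateTime ;
    exergame:result _:result .
_:result   a exergame:Result ;
    exergame:metricRelation _:rel1 , _:rel2 , _:rel3 .
_:rel1     a exergame:MetricRelation ;
    exergame:metricName exergame-metric:Success ;
    exergame:metricValue _:seq .
_:seq      a rdf:Seq ;                       # one member per exercise iteration
    rdf:_1 true ; rdf:_2 true ; rdf:_3 false ;
    rdf:_4 true ; rdf:_5 false ; rdf:_6 true .
```

A single-iteration metric attaches its value as a plain typed literal;
two or more iterations go through an `rdf:Seq` whose numbered membership
properties `rdf:_1..rdf:_n` preserve order. Sessions, results, relations
and sequences are blank nodes by default (as in the published dataset),
with an optional skolemization switch for triplestore upload.

## Worked example

```r
library(exergraph)

fx <- sideraises_fixture()          # the published SideRaises game + session
g  <- session_to_graph(fx$session)  # emit as RDF
graph_size(g)
#> [1] 43

cat(substr(serialize_graph(g, "turtle"), 1, 300))  # or "rdfxml", "ntriples"

validate_graph(g)                   # structural + anonymization rules
#> [1] code   node   detail     <0 rows> (clean)

run_query(g, "
  PREFIX exergame: <http://purl.org/net/exergame/ns#>
  SELECT (COUNT(DISTINCT ?p) AS ?n) WHERE { ?s exergame:player ?p }")
#>   n
#> 1 1

metric_at_iteration(g, "http://purl.org/net/exergame/metric#Success", 3)
#>                                        player             startDateTime value
#> 1 http://www.fitforall.gr/resources/player162 2014-09-22T18:09:39+02:00 false
```

The third Success iteration is `false` — the session's player failed that
repetition — and the row carries the player IRI and session date, which is
the access pattern a monitoring dashboard needs.

A full synthetic pilot (14 players, 6 visits, 7 games per visit):

```r
pilot <- simulate_pilot(default_pilot_config())
length(pilot$sessions)      #> 588
graph_size(pilot$graph)     #> ~29000 triples
nrow(validate_graph(pilot$graph))  #> 0
```

`sessions_to_csv()` / `rows_to_sessions()` close the loop with tabular
logs: the simulator's CSV, converted back through the R2RML-inspired
mapping, reproduces the simulator's RDF bit-for-bit after
canonicalization.

A command-line interface wrapping these functions is installed at
`system.file("cli", "exergraph.R", package = "exergraph")` with
subcommands `simulate`, `validate`, `query`, `convert`, `describe-game`
and `canonicalize`.

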