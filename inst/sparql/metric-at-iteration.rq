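# All values of metric {{metric}} at iteration {{iteration}}, with the
# session's player and start date. Reconstruction of the dataset's
# canonical retrieval path (session -> result -> metric relation ->
# metric name/value -> rdf:_n member); substitute {{metric}} with the
# metric IRI and {{iteration}} with the 1-based iteration index.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX exergame: <http://purl.org/net/exergame/ns#>

SELECT ?player ?startDateTime ?value
WHERE {
  ?session exergame:player ?player ;
           exergame:startDateTime ?startDateTime ;
           exergame:result ?result .
  ?result exergame:metricRelation ?relation .
  ?relation exergame:metricName <{{metric}}> ;
            exergame:metricValue ?valueNode .
  ?valueNode rdf:_{{iteration}} ?value .
}
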