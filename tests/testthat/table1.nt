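# Hand-encoded N-Triples of the published SideRaises session triple table
# (blank-node labels follow the table's abbreviations; the shared
# _:genid... prefix is dropped). The published excerpt shows the session
# and result nodes, the three metric-relation links, and the full Success
# relation with its six-member rdf:Seq; the rdf:type triple on the Success
# relation node is implied by the relation class and included here.
# Timestamps are +02:00 (the printed offset sign is mangled in extraction)
# and the metric namespace misprint purl.com is normalized to purl.org.
_:SideRaisesGameSession <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://purl.org/net/exergame/ns#GameSession> .
_:SideRaisesGameSession <http://purl.org/net/exergame/ns#result> _:SideRaisesGameResult .
_:SideRaisesGameSession <http://purl.org/net/exergame/ns#site> <http://www.fitforall.gr/resources/MedicalPhysicsLaboratoryAuth> .
_:SideRaisesGameSession <http://purl.org/net/exergame/ns#startDateTime> "2014-09-22T18:09:39+02:00"^^<http://www.w3.org/2001/XMLSchema#dateTime> .
_:SideRaisesGameSession <http://purl.org/net/exergame/ns#endDateTime> "2014-09-22T18:09:39+02:00"^^<http://www.w3.org/2001/XMLSchema#dateTime> .
_:SideRaisesGameSession <http://purl.org/net/exergame/ns#player> <http://www.fitforall.gr/resources/player162> .
_:SideRaisesGameSession <http://purl.org/net/exergame/ns#game> <http://www.fitforall.gr/resources/SideRaisesGame> .
_:SideRaisesGameResult <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://purl.org/net/exergame/ns#Result> .
_:SideRaisesGameResult <http://purl.org/net/exergame/ns#metricRelation> _:MetricRelation1 .
_:SideRaisesGameResult <http://purl.org/net/exergame/ns#metricRelation> _:MetricRelation2 .
_:SideRaisesGameResult <http://purl.org/net/exergame/ns#metricRelation> _:MetricRelation3 .
_:MetricRelation1 <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://purl.org/net/exergame/ns#MetricRelation> .
_:MetricRelation1 <http://purl.org/net/exergame/ns#metricName> <http://purl.org/net/exergame/metric#Success> .
_:MetricRelation1 <http://purl.org/net/exergame/ns#metricValue> _:node197jv5qonx686 .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://www.w3.org/1999/02/22-rdf-syntax-ns#Seq> .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#_1> "true"^^<http://www.w3.org/2001/XMLSchema#boolean> .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#_2> "true"^^<http://www.w3.org/2001/XMLSchema#boolean> .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#_3> "false"^^<http://www.w3.org/2001/XMLSchema#boolean> .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#_4> "true"^^<http://www.w3.org/2001/XMLSchema#boolean> .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#_5> "false"^^<http://www.w3.org/2001/XMLSchema#boolean> .
_:node197jv5qonx686 <http://www.w3.org/1999/02/22-rdf-syntax-ns#_6> "true"^^<http://www.w3.org/2001/XMLSchema#boolean> .
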