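PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT * WHERE {
  ?name_1 openbiodiv:relatedName ?name_2 .
  ?name_1 rdfs:label ?label_1 .
  ?name_2 rdfs:label ?label_2 .
} LIMIT 100
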