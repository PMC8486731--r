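PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
SELECT ?label (COUNT(?tnu) AS ?nmentions)
WHERE {
  ?s rdf:type openbiodiv:ScientificName ;
     rdfs:label ?label ;
     dwc:specificEpithet ?species ;
     dwc:genus ?genus .
  ?tnu pkm:mentions ?s .
}
GROUP BY ?s ?label
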