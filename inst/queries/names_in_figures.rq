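PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
PREFIX doco: <http://purl.org/spar/doco/>
SELECT (MAX(?name) AS ?name) (COUNT(DISTINCT ?a) AS ?nmentions)
WHERE {
  ?s rdf:type openbiodiv:ScientificName ;
     rdfs:label ?name .
  ?tnu pkm:mentions ?s .
  ?a po:contains ?tnu .
  ?a rdf:type doco:Figure .
}
GROUP BY ?s
ORDER BY DESC(?nmentions)
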