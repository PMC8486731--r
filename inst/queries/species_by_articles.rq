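PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
PREFIX fabio: <http://purl.org/spar/fabio/>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
SELECT (SAMPLE(?name) AS ?n) (COUNT(DISTINCT ?a) AS ?narticles)
WHERE {
  ?s a openbiodiv:ScientificName ;
     rdfs:label ?name ;
     dwc:specificEpithet ?sp ;
     dwc:genus ?g .
  ?tnu pkm:mentions ?s .
  ?a po:contains+ ?tnu ;
     a fabio:JournalArticle .
}
GROUP BY ?s
ORDER BY DESC(?narticles)
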