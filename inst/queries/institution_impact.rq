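PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
PREFIX fabio: <http://purl.org/spar/fabio/>
PREFIX prism: <http://prismstandard.org/namespaces/basic/2.0/>
SELECT ?institution_name (COUNT(DISTINCT ?treatment) AS ?times_mentioned)
       (COUNT(DISTINCT ?title) AS ?articles)
       (GROUP_CONCAT(DISTINCT ?title; SEPARATOR=", ") AS ?doi_of_articles)
       (GROUP_CONCAT(DISTINCT ?name; SEPARATOR=", ") AS ?names_mentioned)
       (COUNT(DISTINCT ?name) AS ?number_of_taxa)
       (COUNT(DISTINCT ?tnu) AS ?number_of_tnus)
WHERE {
  BIND("{{institution_name}}" AS ?institution_name)
  BIND("{{institution_code}}" AS ?institution_code)
  ?treatment openbiodiv:institutionName|dwc:institutionCode|dwc:collectionCode ?institution_code .
  ?treatment (po:contains)|(po:contains/po:contains) ?tnu ;
             a openbiodiv:Treatment .
  ?tnu pkm:mentions ?s .
  ?s a openbiodiv:ScientificName ;
     rdfs:label ?name .
  ?article po:contains ?treatment ;
           rdf:type fabio:JournalArticle ;
           prism:doi ?title .
}
GROUP BY ?institution_name
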