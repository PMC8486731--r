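PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX foaf: <http://xmlns.com/foaf/0.1/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX dcterms: <http://purl.org/dc/terms/>
PREFIX fabio: <http://purl.org/spar/fabio/>
SELECT (SAMPLE(?name) AS ?name) (COUNT(DISTINCT ?paper) AS ?npapers)
WHERE {
  ?author rdf:type foaf:Person ;
          rdfs:label ?name .
  ?paper dcterms:creator ?author .
  ?paper a fabio:ResearchPaper .
}
GROUP BY ?author
ORDER BY DESC(?npapers)
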