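PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX dwciri: <http://rs.tdwg.org/dwc/iri/>
PREFIX skos: <http://www.w3.org/2004/02/skos/core#>
PREFIX prism: <http://prismstandard.org/namespaces/basic/2.0/>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
SELECT *
WHERE {
  ?n rdfs:label "{{family_label}}" .
  ?c openbiodiv:scientificName ?n .
  ?s skos:broader ?c .
  ?s openbiodiv:scientificName ?sn .
  ?sn dwc:genus ?vgenus .
  ?tnu pkm:mentions ?name ;
       dwciri:taxonomicStatus openbiodiv:TaxonomicDiscovery .
  ?name dwc:genus ?vgenus ;
        rdfs:label ?verbatim .
  ?article po:contains+ ?tnu ;
           prism:publicationDate ?date .
}
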