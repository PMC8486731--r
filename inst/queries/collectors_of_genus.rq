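PREFIX dc: <http://purl.org/dc/elements/1.1/>
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
SELECT ?label ?recorder ?eventDate
WHERE {
  ?article dc:title ?articleTitle ;
           po:contains ?treatment .
  ?treatment rdf:type openbiodiv:Treatment ;
             po:contains ?materials ;
             po:contains ?nomenclature .
  ?materials rdf:type openbiodiv:MaterialsExamined ;
             dwc:occurrenceID ?occurrence ;
             dwc:eventID ?event .
  ?occurrence dwc:recordedBy ?recorder .
  ?event dwc:eventDate ?eventDate .
  ?nomenclature rdf:type openbiodiv:NomenclatureSection ;
                po:contains ?tnu .
  ?tnu pkm:mentions ?name .
  ?name rdfs:label ?label ;
        dwc:genus "{{genus}}" .
}
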