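PREFIX datacite: <http://purl.org/spar/datacite/>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
PREFIX fabio: <http://purl.org/spar/fabio/>
PREFIX prism: <http://prismstandard.org/namespaces/basic/2.0/>
SELECT ?materialsExamined ?genomicLabel ?system ?name ?label ?institution ?doi
WHERE {
  ?genomicIdentifier datacite:usesIdentifierScheme ?system ;
                     rdfs:label ?genomicLabel .
  FILTER (?system IN (datacite:genbank, datacite:boldsystems))
  ?materialsExamined openbiodiv:mentionsIdentifier ?genomicIdentifier ;
                     a openbiodiv:MaterialsExamined ;
                     po:contains ?holotypeDescr .
  ?holotypeDescr a openbiodiv:HolotypeDescription .
  ?treatment po:contains ?materialsExamined ;
             a openbiodiv:Treatment ;
             po:contains ?nomenclature ;
             dwc:institutionID ?institution .
  ?nomenclature a openbiodiv:NomenclatureSection ;
                po:contains ?tnu .
  ?tnu pkm:mentions ?name .
  ?name rdfs:label ?label .
  ?article a fabio:JournalArticle ;
           po:contains ?treatment ;
           prism:doi ?doi .
}
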