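PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
PREFIX openbiodiv: <http://openbiodiv.net/>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
PREFIX pkm: <http://proton.semanticweb.org/protonkm#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT ?family (COUNT(DISTINCT ?treatment) AS ?treatments) ?inst ?instName
WHERE {
  ?tnu pkm:mentions ?scName .
  ?scName dwc:family ?family .
  ?treatment (po:contains)|(po:contains/po:contains) ?tnu ;
             a openbiodiv:Treatment ;
             dwc:institutionID ?inst .
  ?inst a openbiodiv:Institution ;
        openbiodiv:institutionName ?instName .
}
GROUP BY ?inst ?instName ?family
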