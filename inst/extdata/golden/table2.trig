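@prefix openbiodiv: <http://openbiodiv.net/> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix dwc: <http://rs.tdwg.org/dwc/terms/> .

openbiodiv:Fragments {
    openbiodiv:5BBC353E-CC39-4F2C-B4CE-DC2636CB2DC8 rdf:type openbiodiv:ScientificName ;
        rdfs:label "Zelus casii" ;
        dwc:genus "Zelus" ;
        dwc:specificEpithet "casii" ;
        dwc:verbatimTaxonRank "species" ;
        openbiodiv:hasGbifTaxon openbiodiv:F1DD0CF0-217D-422B-BAA4-58901976D7B4-9146644-scName .
}
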