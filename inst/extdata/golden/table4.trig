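@prefix openbiodiv: <http://openbiodiv.net/> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix foaf: <http://xmlns.com/foaf/0.1/> .
@prefix datacite: <http://purl.org/spar/datacite/> .
@prefix orcid: <https://orcid.org/> .

openbiodiv:Fragments {
    openbiodiv:51DE6A4F-4651-4540-A54D-21A307105405 rdf:type foaf:Person ;
        rdfs:label "Guanyang Zhang" ;
        foaf:surname "Zhang" ;
        openbiodiv:affiliation "Florida Museum of Natural History, University of Florida, Gainesville, FL, USA" ;
        datacite:hasIdentifier orcid:0000-0003-4389-4270 .
}
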