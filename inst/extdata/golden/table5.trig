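@prefix openbiodiv: <http://openbiodiv.net/> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix fabio: <http://purl.org/spar/fabio/> .
@prefix prism: <http://prismstandard.org/namespaces/basic/2.0/> .
@prefix dc: <http://purl.org/dc/elements/1.1/> .
@prefix dcterms: <http://purl.org/dc/terms/> .
@prefix deo: <http://purl.org/spar/deo/> .
@prefix po: <http://www.essepuntato.it/2008/12/pattern#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

openbiodiv:Fragments {
    openbiodiv:570F0E79-5632-FF88-A155-73625E50C567 rdf:type fabio:JournalArticle ;
        prism:doi "10.3897/BDJ.4.e8150" ;
        dc:publisher "Pensoft Publishers" ;
        prism:publicationDate "2016-07-08"^^xsd:date ;
        dcterms:publisher openbiodiv:09EAAD23-3913-421E-9249-3FAAF1BA12DB .
    openbiodiv:0BD7ED36-1192-47A5-99F9-113998EF3099 rdf:type deo:Introduction ;
        po:isContainedBy openbiodiv:570F0E79-5632-FF88-A155-73625E50C567 .
}
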