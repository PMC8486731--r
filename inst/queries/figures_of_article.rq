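PREFIX fabio: <http://purl.org/spar/fabio/>
PREFIX prism: <http://prismstandard.org/namespaces/basic/2.0/>
PREFIX doco: <http://purl.org/spar/doco/>
PREFIX po: <http://www.essepuntato.it/2008/12/pattern#>
SELECT ?f
WHERE {
  ?a a fabio:JournalArticle ;
     prism:doi "{{doi}}" .
  ?f a doco:Figure .
  ?a po:contains ?f .
}
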