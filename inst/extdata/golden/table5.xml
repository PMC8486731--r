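<article>
  <front>
    <journal-meta><publisher><publisher-name>Pensoft Publishers</publisher-name></publisher></journal-meta>
    <article-meta>
      <article-id pub-id-type="doi">10.3897/BDJ.4.e8150</article-id>
      <pub-date iso-8601-date="2016-07-08"/>
    </article-meta>
  </front>
  <body>
    <sec sec-type="introduction"/>
  </body>
</article>
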