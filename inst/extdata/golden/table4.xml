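<article>
  <front>
    <article-meta>
      <contrib-group>
        <contrib contrib-type="author" corresp="no">
          <name name-style="western"><surname>Zhang</surname><given-names>Guanyang Zhang</given-names></name>
          <uri content-type="orcid">https://orcid.org/0000-0003-4389-4270</uri>
          <xref ref-type="aff" rid="3">3</xref>
        </contrib>
      </contrib-group>
      <aff id="A3"><label>3</label><addr-line>Florida Museum of Natural History, University of Florida, Gainesville, FL, USA</addr-line></aff>
    </article-meta>
  </front>
</article>
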