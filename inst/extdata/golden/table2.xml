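<tp:taxon-name xmlns:tp="http://www.plazi.org/taxpub"><tp:taxon-name-part taxon-name-part-type="genus" reg="Zelus">P.</tp:taxon-name-part><tp:taxon-name-part taxon-name-part-type="species" reg="casii">casii</tp:taxon-name-part></tp:taxon-name>
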