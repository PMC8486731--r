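status_text,status_class
sp. nov.,openbiodiv:TaxonomicDiscovery
sp. n.,openbiodiv:TaxonomicDiscovery
spec. nov.,openbiodiv:TaxonomicDiscovery
gen. nov.,openbiodiv:TaxonomicDiscovery
gen. n.,openbiodiv:TaxonomicDiscovery
fam. nov.,openbiodiv:TaxonomicDiscovery
comb. nov.,openbiodiv:ReplacementName
comb. n.,openbiodiv:ReplacementName
nom. nov.,openbiodiv:ReplacementName
nomen novum,openbiodiv:ReplacementName
stat. nov.,openbiodiv:ReplacementName
nomen dubium,openbiodiv:UnavailableName
nomen nudum,openbiodiv:UnavailableName
nom. inval.,openbiodiv:UnavailableName
unavailable name,openbiodiv:UnavailableName
stat. rev.,openbiodiv:AvailableName
nom. reval.,openbiodiv:AvailableName
available name,openbiodiv:AvailableName
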