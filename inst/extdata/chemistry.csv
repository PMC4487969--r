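net,wash,mg_per_m2
icon_maxx,0,59.7
icon_maxx,20,29
icon_maxx,27,6.3
ctn,0,13.2
ctn,4,0.5
ctn,20,0.2
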