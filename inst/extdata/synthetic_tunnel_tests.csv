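net,wash,n_released,n_penetrated,n_fed,n_dead
icon_maxx,0,100,18,1,100
ctn,0,100,15,1,100
icon_maxx,20,100,25,10,100
ctn,20,100,79,78,9
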