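net,wash,replicate,n_exposed,n_kd60,n_dead24
ctn,0,1,5,5,5
ctn,0,2,5,5,5
ctn,0,3,5,5,5
ctn,0,4,5,5,5
ctn,0,5,5,5,5
ctn,0,6,5,5,5
ctn,0,7,5,5,5
ctn,0,8,5,5,5
ctn,0,9,5,5,5
ctn,0,10,5,5,5
ctn,1,1,5,5,5
ctn,1,2,5,5,5
ctn,1,3,5,5,5
ctn,1,4,5,5,5
ctn,1,5,5,5,5
ctn,1,6,5,5,5
ctn,1,7,5,5,5
ctn,1,8,5,5,5
ctn,1,9,5,5,4
ctn,1,10,5,5,4
ctn,2,1,5,5,5
ctn,2,2,5,5,5
ctn,2,3,5,5,5
ctn,2,4,5,5,5
ctn,2,5,5,5,4
ctn,2,6,5,5,4
ctn,2,7,5,5,4
ctn,2,8,5,5,4
ctn,2,9,5,5,4
ctn,2,10,5,4,4
ctn,3,1,5,5,5
ctn,3,2,5,5,5
ctn,3,3,5,5,4
ctn,3,4,5,5,4
ctn,3,5,5,5,4
ctn,3,6,5,5,4
ctn,3,7,5,5,4
ctn,3,8,5,5,4
ctn,3,9,5,4,4
ctn,3,10,5,4,4
ctn,4,1,5,5,4
ctn,4,2,5,5,4
ctn,4,3,5,5,4
ctn,4,4,5,5,4
ctn,4,5,5,5,4
ctn,4,6,5,5,4
ctn,4,7,5,5,4
ctn,4,8,5,5,4
ctn,4,9,5,4,4
ctn,4,10,5,4,3
icon_maxx,0,1,5,5,5
icon_maxx,0,2,5,5,5
icon_maxx,0,3,5,5,5
icon_maxx,0,4,5,5,5
icon_maxx,0,5,5,5,5
icon_maxx,0,6,5,5,5
icon_maxx,0,7,5,5,5
icon_maxx,0,8,5,5,5
icon_maxx,0,9,5,5,5
icon_maxx,0,10,5,5,5
icon_maxx,1,1,5,5,5
icon_maxx,1,2,5,5,5
icon_maxx,1,3,5,5,5
icon_maxx,1,4,5,5,5
icon_maxx,1,5,5,5,5
icon_maxx,1,6,5,5,5
icon_maxx,1,7,5,5,5
icon_maxx,1,8,5,5,5
icon_maxx,1,9,5,5,5
icon_maxx,1,10,5,5,5
icon_maxx,2,1,5,5,5
icon_maxx,2,2,5,5,5
icon_maxx,2,3,5,5,5
icon_maxx,2,4,5,5,5
icon_maxx,2,5,5,5,5
icon_maxx,2,6,5,5,5
icon_maxx,2,7,5,5,5
icon_maxx,2,8,5,5,5
icon_maxx,2,9,5,5,5
icon_maxx,2,10,5,4,4
icon_maxx,3,1,5,5,5
icon_maxx,3,2,5,5,5
icon_maxx,3,3,5,5,5
icon_maxx,3,4,5,5,5
icon_maxx,3,5,5,5,5
icon_maxx,3,6,5,5,5
icon_maxx,3,7,5,5,5
icon_maxx,3,8,5,5,5
icon_maxx,3,9,5,5,5
icon_maxx,3,10,5,4,4
icon_maxx,4,1,5,5,5
icon_maxx,4,2,5,5,5
icon_maxx,4,3,5,5,5
icon_maxx,4,4,5,5,5
icon_maxx,4,5,5,5,5
icon_maxx,4,6,5,5,5
icon_maxx,4,7,5,5,5
icon_maxx,4,8,5,5,5
icon_maxx,4,9,5,4,4
icon_maxx,4,10,5,4,4
icon_maxx,5,1,5,5,5
icon_maxx,5,2,5,5,5
icon_maxx,5,3,5,5,5
icon_maxx,5,4,5,5,5
icon_maxx,5,5,5,5,5
icon_maxx,5,6,5,5,5
icon_maxx,5,7,5,5,5
icon_maxx,5,8,5,5,5
icon_maxx,5,9,5,4,4
icon_maxx,5,10,5,4,4
icon_maxx,6,1,5,5,5
icon_maxx,6,2,5,5,5
icon_maxx,6,3,5,5,5
icon_maxx,6,4,5,5,5
icon_maxx,6,5,5,5,5
icon_maxx,6,6,5,5,5
icon_maxx,6,7,5,5,5
icon_maxx,6,8,5,5,4
icon_maxx,6,9,5,4,4
icon_maxx,6,10,5,4,4
icon_maxx,7,1,5,5,5
icon_maxx,7,2,5,5,5
icon_maxx,7,3,5,5,5
icon_maxx,7,4,5,5,5
icon_maxx,7,5,5,5,5
icon_maxx,7,6,5,5,5
icon_maxx,7,7,5,5,5
icon_maxx,7,8,5,5,4
icon_maxx,7,9,5,4,4
icon_maxx,7,10,5,4,4
icon_maxx,8,1,5,5,5
icon_maxx,8,2,5,5,5
icon_maxx,8,3,5,5,5
icon_maxx,8,4,5,5,5
icon_maxx,8,5,5,5,5
icon_maxx,8,6,5,5,5
icon_maxx,8,7,5,5,4
icon_maxx,8,8,5,5,4
icon_maxx,8,9,5,4,4
icon_maxx,8,10,5,4,4
icon_maxx,9,1,5,5,5
icon_maxx,9,2,5,5,5
icon_maxx,9,3,5,5,5
icon_maxx,9,4,5,5,5
icon_maxx,9,5,5,5,5
icon_maxx,9,6,5,5,5
icon_maxx,9,7,5,5,4
icon_maxx,9,8,5,5,4
icon_maxx,9,9,5,4,4
icon_maxx,9,10,5,4,4
icon_maxx,10,1,5,5,5
icon_maxx,10,2,5,5,5
icon_maxx,10,3,5,5,5
icon_maxx,10,4,5,5,5
icon_maxx,10,5,5,5,5
icon_maxx,10,6,5,5,4
icon_maxx,10,7,5,5,4
icon_maxx,10,8,5,5,4
icon_maxx,10,9,5,4,4
icon_maxx,10,10,5,4,4
icon_maxx,11,1,5,5,5
icon_maxx,11,2,5,5,5
icon_maxx,11,3,5,5,5
icon_maxx,11,4,5,5,5
icon_maxx,11,5,5,5,5
icon_maxx,11,6,5,5,4
icon_maxx,11,7,5,5,4
icon_maxx,11,8,5,5,4
icon_maxx,11,9,5,4,4
icon_maxx,11,10,5,4,4
icon_maxx,12,1,5,5,5
icon_maxx,12,2,5,5,5
icon_maxx,12,3,5,5,5
icon_maxx,12,4,5,5,5
icon_maxx,12,5,5,5,4
icon_maxx,12,6,5,5,4
icon_maxx,12,7,5,5,4
icon_maxx,12,8,5,5,4
icon_maxx,12,9,5,4,4
icon_maxx,12,10,5,4,4
icon_maxx,13,1,5,5,5
icon_maxx,13,2,5,5,5
icon_maxx,13,3,5,5,5
icon_maxx,13,4,5,5,5
icon_maxx,13,5,5,5,4
icon_maxx,13,6,5,5,4
icon_maxx,13,7,5,5,4
icon_maxx,13,8,5,5,4
icon_maxx,13,9,5,4,4
icon_maxx,13,10,5,4,4
icon_maxx,14,1,5,5,5
icon_maxx,14,2,5,5,5
icon_maxx,14,3,5,5,5
icon_maxx,14,4,5,5,4
icon_maxx,14,5,5,5,4
icon_maxx,14,6,5,5,4
icon_maxx,14,7,5,5,4
icon_maxx,14,8,5,5,4
icon_maxx,14,9,5,4,4
icon_maxx,14,10,5,4,4
icon_maxx,15,1,5,5,5
icon_maxx,15,2,5,5,5
icon_maxx,15,3,5,5,5
icon_maxx,15,4,5,5,4
icon_maxx,15,5,5,5,4
icon_maxx,15,6,5,5,4
icon_maxx,15,7,5,5,4
icon_maxx,15,8,5,5,4
icon_maxx,15,9,5,4,4
icon_maxx,15,10,5,4,4
icon_maxx,16,1,5,5,5
icon_maxx,16,2,5,5,5
icon_maxx,16,3,5,5,5
icon_maxx,16,4,5,5,4
icon_maxx,16,5,5,5,4
icon_maxx,16,6,5,5,4
icon_maxx,16,7,5,5,4
icon_maxx,16,8,5,5,4
icon_maxx,16,9,5,4,4
icon_maxx,16,10,5,4,4
icon_maxx,17,1,5,5,5
icon_maxx,17,2,5,5,5
icon_maxx,17,3,5,5,4
icon_maxx,17,4,5,5,4
icon_maxx,17,5,5,5,4
icon_maxx,17,6,5,5,4
icon_maxx,17,7,5,5,4
icon_maxx,17,8,5,5,4
icon_maxx,17,9,5,4,4
icon_maxx,17,10,5,4,4
icon_maxx,18,1,5,5,5
icon_maxx,18,2,5,5,5
icon_maxx,18,3,5,5,4
icon_maxx,18,4,5,5,4
icon_maxx,18,5,5,5,4
icon_maxx,18,6,5,5,4
icon_maxx,18,7,5,5,4
icon_maxx,18,8,5,5,4
icon_maxx,18,9,5,4,4
icon_maxx,18,10,5,4,4
icon_maxx,19,1,5,5,5
icon_maxx,19,2,5,5,5
icon_maxx,19,3,5,5,4
icon_maxx,19,4,5,5,4
icon_maxx,19,5,5,5,4
icon_maxx,19,6,5,5,4
icon_maxx,19,7,5,5,4
icon_maxx,19,8,5,5,4
icon_maxx,19,9,5,4,4
icon_maxx,19,10,5,4,4
icon_maxx,20,1,5,5,5
icon_maxx,20,2,5,5,4
icon_maxx,20,3,5,5,4
icon_maxx,20,4,5,5,4
icon_maxx,20,5,5,5,4
icon_maxx,20,6,5,5,4
icon_maxx,20,7,5,5,4
icon_maxx,20,8,5,5,4
icon_maxx,20,9,5,4,4
icon_maxx,20,10,5,4,4
icon_maxx,21,1,5,5,5
icon_maxx,21,2,5,5,4
icon_maxx,21,3,5,5,4
icon_maxx,21,4,5,5,4
icon_maxx,21,5,5,5,4
icon_maxx,21,6,5,5,4
icon_maxx,21,7,5,5,4
icon_maxx,21,8,5,5,4
icon_maxx,21,9,5,4,4
icon_maxx,21,10,5,4,4
icon_maxx,22,1,5,5,5
icon_maxx,22,2,5,5,4
icon_maxx,22,3,5,5,4
icon_maxx,22,4,5,5,4
icon_maxx,22,5,5,5,4
icon_maxx,22,6,5,5,4
icon_maxx,22,7,5,5,4
icon_maxx,22,8,5,5,4
icon_maxx,22,9,5,4,4
icon_maxx,22,10,5,4,4
icon_maxx,23,1,5,5,5
icon_maxx,23,2,5,5,4
icon_maxx,23,3,5,5,4
icon_maxx,23,4,5,5,4
icon_maxx,23,5,5,5,4
icon_maxx,23,6,5,5,4
icon_maxx,23,7,5,5,4
icon_maxx,23,8,5,5,4
icon_maxx,23,9,5,4,4
icon_maxx,23,10,5,4,4
icon_maxx,24,1,5,5,5
icon_maxx,24,2,5,5,4
icon_maxx,24,3,5,5,4
icon_maxx,24,4,5,5,4
icon_maxx,24,5,5,5,4
icon_maxx,24,6,5,5,4
icon_maxx,24,7,5,5,4
icon_maxx,24,8,5,5,4
icon_maxx,24,9,5,4,4
icon_maxx,24,10,5,4,4
icon_maxx,25,1,5,5,4
icon_maxx,25,2,5,5,4
icon_maxx,25,3,5,5,4
icon_maxx,25,4,5,5,4
icon_maxx,25,5,5,5,4
icon_maxx,25,6,5,5,4
icon_maxx,25,7,5,5,4
icon_maxx,25,8,5,5,4
icon_maxx,25,9,5,4,4
icon_maxx,25,10,5,4,4
icon_maxx,26,1,5,5,4
icon_maxx,26,2,5,5,4
icon_maxx,26,3,5,5,4
icon_maxx,26,4,5,5,4
icon_maxx,26,5,5,5,4
icon_maxx,26,6,5,5,4
icon_maxx,26,7,5,5,4
icon_maxx,26,8,5,5,3
icon_maxx,26,9,5,4,3
icon_maxx,26,10,5,4,3
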