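fixation_id,r1,r2,r3,r4
f1,0,0,0,0
f2,0,0,0,0
f3,0,0,0,0
f4,0,0,0,0
f5,1,0,1,1
f6,1,1,1,1
f7,1,1,1,1
f8,1,1,1,0
f9,2,1,2,2
f10,2,2,2,1
f11,2,1,2,1
f12,2,1,2,2
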