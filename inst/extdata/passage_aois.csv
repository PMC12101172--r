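x,y,width,height,line,token
20,30,44,24,0,the
76,30,68,24,0,quick
156,30,68,24,0,brown
236,30,44,24,0,fox
292,30,68,24,0,jumps
20,90,56,24,1,over
88,90,20,24,1,a
120,90,56,24,1,lazy
188,90,104,24,1,sleeping
304,90,44,24,1,dog
20,150,68,24,2,while
100,150,32,24,2,we
144,150,68,24,2,watch
224,150,32,24,2,it
268,150,92,24,2,quietly
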