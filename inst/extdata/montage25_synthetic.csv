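"channel","x","y"
"S01",0,0
"S02",1,0
"S03",2,0
"S04",3,0
"S05",4,0
"S06",0,1
"S07",1,1
"S08",2,1
"S09",3,1
"S10",4,1
"S11",0,2
"S12",1,2
"S13",2,2
"S14",3,2
"S15",4,2
"S16",0,3
"S17",1,3
"S18",2,3
"S19",3,3
"S20",4,3
"S21",0,4
"S22",1,4
"S23",2,4
"S24",3,4
"S25",4,4
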