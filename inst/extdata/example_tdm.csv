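ID,TIME,AMT,II,DV,MDV,WT,ZOP
1,0,100,24,,1,70,0
1,240,,,55.1,0,70,0
1,408,,,60.3,0,70,0
2,0,50,12,,1,45,0
2,240,,,80.2,0,45,0
2,336,,,74.8,0,45,0
3,0,75,24,,1,60,1
3,336,,,110.5,0,60,1
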