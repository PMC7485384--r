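"x","y"
-0.591,-1.596
0.027,-0.12
-1.517,-3.803
-1.363,-2.854
1.178,1.781
-0.934,-1.862
1.324,2.537
0.625,1.694
-0.046,-0.388
-1.004,-2.336
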