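"stratum","x","y"
"S1",12.1116159082007,4.16489622580285
"S2",4.87136704032473,11.9052856235465
"S3",1.41700261169407,2.03130654093501
"S4",0.854243365367939,5.62284860101471
"S5",2.98530816028793,2.10347576230202
"S6",9.70010707115154,2.83500393273037
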