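"phi","n","n_rep","mean_se","sd_se"
0,405,200,1.12339902183243,0.0397126998395102
0.05,405,200,1.11790152580146,0.0385184825650408
0.1,405,200,1.11122298834451,0.0379056836010361
0.15,405,200,1.10716216341484,0.039708124279576
0.2,405,200,1.09941024680754,0.0390331384340127
0.25,405,200,1.08915338906986,0.0417622518083945
0.3,405,200,1.07628758385487,0.0396528867102795
0.35,405,200,1.0598118777632,0.0387579683450194
0.4,405,200,1.04312085872777,0.0398268687392693
0.45,405,200,1.02197106387825,0.0429926804608106
0.5,405,200,0.994674242216304,0.0407649893111697
0.55,405,200,0.959148866798757,0.0437325577311041
0.6,405,200,0.925812820943005,0.0465903553805012
0.65,405,200,0.890651451237476,0.0441522889658046
0.7,405,200,0.831442171940486,0.049167262521231
0.75,405,200,0.781171602085728,0.0504680097118289
0.8,405,200,0.704712106292727,0.0549434618412702
0.85,405,200,0.615959886723847,0.0573142312706479
0.9,405,200,0.498298405025053,0.0623554832188159
0.95,405,200,0.343527668450231,0.0728203911808727
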