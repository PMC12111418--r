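region,size_bp,T_pct,C_pct,A_pct,G_pct
Full genome,16606,25.1,27.4,31.4,16.1
D-loop,945,32.6,21.1,33.5,12.8
PCGs,11403,27.0,28.1,29.4,15.5
tRNAs,1563,26.8,21.4,28.0,23.8
rRNAs,2640,20.1,24.5,34.7,20.7
PCGs-1st,3801,20.9,26.4,27.1,25.6
PCGs-2nd,3801,40.4,27.3,18.6,13.7
PCGs-3rd,3801,19.7,30.6,42.4,7.3
ATP6,684,27.2,28.4,30.6,13.9
ATP8,165,23.6,28.5,36.4,11.5
COX1,1551,28.9,26.4,27.2,17.5
COX2,691,26.5,26.6,30.7,16.2
COX3,785,26.5,28.9,27.5,17.1
CYTB,1141,28.1,28.4,28.3,15.2
ND1,975,26.1,29.6,29.1,15.2
ND2,1045,23.2,30.4,34.1,12.3
ND3,349,28.4,29.2,28.4,14.0
ND4,1381,25.6,29.2,31.2,14.0
ND4L,297,29.0,28.3,26.9,15.8
ND5,1824,24.7,30.3,32.4,12.6
ND6,522,41.0,13.2,13.0,32.8
16S rRNA,1684,20.6,23.1,36.3,20.0
12S rRNA,956,19.2,27.0,31.9,21.9
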