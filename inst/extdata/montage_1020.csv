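label,x,y,z
Fp1,-0.029437,0.083917,-0.006990
Fp2,0.029872,0.084896,-0.007080
AF3,-0.033701,0.076837,0.021227
AF4,0.035712,0.077726,0.021956
F3,-0.050244,0.053111,0.042192
F4,0.051836,0.054305,0.040814
F7,-0.070263,0.042474,-0.011420
F8,0.073043,0.044422,-0.012000
FC5,-0.077215,0.018643,0.024460
FC6,0.079534,0.019936,0.024438
C3,-0.065358,-0.011632,0.064358
C4,0.067118,-0.010900,0.063580
T7,-0.084161,-0.016019,-0.009346
T8,0.085080,-0.015020,-0.009490
CP5,-0.079592,-0.046551,0.030949
CP6,0.083322,-0.046101,0.031206
P3,-0.053007,-0.078788,0.055940
P4,0.055667,-0.078560,0.056561
P7,-0.072434,-0.073453,-0.002487
P8,0.073056,-0.073068,-0.002540
PO3,-0.036511,-0.100853,0.037167
PO4,0.036782,-0.100849,0.036397
PO7,-0.054840,-0.097528,0.002792
PO8,0.055667,-0.097625,0.002730
O1,-0.029413,-0.112449,0.008839
O2,0.029843,-0.112156,0.008800
Fz,0.000312,0.058512,0.066462
Cz,0.000401,-0.009167,0.100244
Pz,0.000325,-0.081115,0.082615
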