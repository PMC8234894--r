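animal,sire,dam,birth_year,sex
G0_0001,0,0,2000,M
G0_0002,0,0,2000,F
G0_0003,0,0,2000,M
G0_0004,0,0,2000,F
G0_0005,0,0,2000,M
G0_0006,0,0,2000,F
G1_0001,G0_0001,G0_0002,2001,M
G1_0002,G0_0001,G0_0002,2001,F
G1_0003,G0_0003,G0_0006,2001,F
G1_0004,G0_0003,G0_0006,2001,F
G1_0005,G0_0003,G0_0004,2001,M
G2_0001,G1_0005,G1_0004,2002,F
G2_0002,G1_0005,G1_0004,2002,M
G2_0003,G1_0001,G1_0002,2002,M
G2_0004,G1_0001,G1_0002,2002,F
G2_0005,G1_0001,G1_0004,2002,M
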