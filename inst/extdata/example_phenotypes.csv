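animal,trait,contemporary_group,parity_class,birth_year
G0_0001,0.178479599717016,y2000_g01,1,2000
G0_0002,0.926733672234259,y2000_g01,3,2000
G0_0003,0.854148730098322,y2000_g01,2,2000
G0_0004,1.75534206836788,y2000_g01,4,2000
G0_0005,2.08632346179228,y2000_g01,2,2000
G0_0006,0.920140577016905,y2000_g01,4,2000
G1_0001,-0.356559647833885,y2001_g01,1,2001
G1_0002,0.0803819694956278,y2001_g01,2,2001
G1_0003,2.07128696487115,y2001_g01,4,2001
G1_0004,0.345222263769847,y2001_g01,2,2001
G1_0005,-0.134691648744466,y2001_g01,3,2001
G2_0001,0.377537647400463,y2002_g01,1,2002
G2_0002,2.38828475469795,y2002_g01,1,2002
G2_0003,0.294990891910813,y2002_g01,1,2002
G2_0004,1.21492265788463,y2002_g01,2,2002
G2_0005,1.40094156234087,y2002_g01,1,2002
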