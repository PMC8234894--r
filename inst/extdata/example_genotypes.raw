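FID IID PAT MAT SEX PHENOTYPE snp00001_A snp00002_A snp00003_A snp00004_A snp00005_A snp00006_A snp00007_A snp00008_A snp00009_A snp00010_A snp00011_A snp00012_A
G1_0004 G1_0004 0 0 0 -9 0 0 1 0 0 0 0 1 0 0 0 1
G1_0005 G1_0005 0 0 0 -9 0 0 1 0 1 1 2 0 0 0 2 1
G2_0001 G2_0001 0 0 0 -9 0 0 1 0 1 1 1 0 0 0 1 2
G2_0002 G2_0002 0 0 0 -9 0 0 1 0 1 1 1 1 0 0 1 1
G2_0003 G2_0003 0 0 0 -9 0 0 1 0 0 0 0 2 0 1 1 2
G2_0004 G2_0004 0 0 0 -9 0 0 0 0 0 0 2 1 0 1 2 2
G2_0005 G2_0005 0 0 0 -9 0 0 2 0 0 0 0 1 0 0 1 1
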