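snp_id	chrom	pos
snp00001	1	8333333
snp00002	1	25000000
snp00003	1	41666667
snp00004	1	58333333
snp00005	1	75000000
snp00006	1	91666667
snp00007	2	8333333
snp00008	2	25000000
snp00009	2	41666667
snp00010	2	58333333
snp00011	2	75000000
snp00012	2	91666667
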