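# synthetic phenotype-SNP association scores (similarity scale)
# phenotype	snp	score
P1	G1	3
P1	G2	3
P2	G1	3
P3	G2	1
P3	G3	3
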