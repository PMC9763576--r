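rsid	chrom	effect_allele	beta	se
rs1801133	1	A	0.063	0.042
rs2275565	1	T	0.044	0.044
rs9369898	6	A	-0.012	0.037
rs7130284	11	T	-0.008	0.053
rs154657	16	A	0.043	0.037
rs4660306	1	T	0.000	0.038
rs548987	6	C	0.014	0.063
rs42648	7	A	-0.013	0.037
rs1801222	10	A	0.049	0.038
rs2251468	12	A	-0.047	0.037
rs838133	19	A	0.013	0.037
rs12780845	10	A	-0.081	0.041
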