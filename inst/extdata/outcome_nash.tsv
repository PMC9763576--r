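rsid	chrom	effect_allele	beta	se
rs1801133	1	A	-0.037	0.168
rs2275565	1	T	-0.020	0.173
rs9369898	6	A	0.297	0.146
rs7130284	11	T	-0.244	0.210
rs154657	16	A	0.144	0.147
rs4660306	1	T	-0.036	0.150
rs548987	6	C	-0.216	0.251
rs42648	7	A	-0.069	0.147
rs1801222	10	A	-0.057	0.153
rs2251468	12	A	0.252	0.146
rs838133	19	A	0.099	0.148
rs12780845	10	A	0.236	0.165
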