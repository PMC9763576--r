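rsid	chrom	effect_allele	beta	se
rs1801133	1	A	-0.142	0.058
rs2275565	1	T	-0.020	0.060
rs9369898	6	A	0.052	0.050
rs7130284	11	T	0.029	0.072
rs154657	16	A	0.054	0.051
rs4660306	1	T	0.102	0.052
rs548987	6	C	-0.114	0.087
rs42648	7	A	0.000	0.051
rs1801222	10	A	-0.030	0.053
rs2251468	12	A	0.026	0.050
rs838133	19	A	0.025	0.051
rs12780845	10	A	-0.021	0.057
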