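rsid	chrom	effect_allele	eaf	beta	se	pvalue
rs1801133	1	A	0.34	0.1583	0.007	4.34E-104
rs2275565	1	T	0.21	-0.0542	0.009	1.96E-10
rs9369898	6	A	0.62	0.0449	0.007	2.17E-10
rs7130284	11	T	0.07	-0.1242	0.013	1.88E-20
rs154657	16	A	0.45	0.0963	0.007	1.74E-43
rs4660306	1	T	0.33	0.0435	0.007	2.33E-09
rs548987	6	C	0.13	0.0597	0.01	1.12E-08
rs42648	7	A	0.40	-0.0395	0.007	1.97E-08
rs1801222	10	A	0.34	0.0453	0.007	8.43E-10
rs2251468	12	A	0.65	-0.0512	0.007	1.28E-12
rs838133	19	A	0.45	0.0422	0.007	7.48E-09
rs12780845	10	A	0.65	0.0529	0.009	7.80E-10
rs12134663	1	C	0.31	0.0711	0.009	3.10E-15
rs957140	16	G	0.44	0.0404	0.007	6.40E-12
rs12921383	11	T	0.09	-0.0566	0.010	8.90E-11
rs7422339	2	A	0.68	0.0988	0.016	4.60E-10
rs2851391	2	T	0.52	0.0370	0.006	1.30E-09
rs0cand18	3	G	0.27	0.0412	0.007	4.00E-09
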