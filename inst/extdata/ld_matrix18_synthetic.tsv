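rsid	rs1801133	rs2275565	rs9369898	rs7130284	rs154657	rs4660306	rs548987	rs42648	rs1801222	rs2251468	rs838133	rs12780845	rs12134663	rs957140	rs12921383	rs7422339	rs2851391	rs0cand18
rs1801133	1	0	0	0	0	0	0	0	0	0	0	0	0.9	0	0	0	0	0
rs2275565	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs9369898	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
rs7130284	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0.9	0	0	0
rs154657	0	0	0	0	1	0	0	0	0	0	0	0	0	0.9	0	0	0	0
rs4660306	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0
rs548987	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0
rs42648	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0
rs1801222	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
rs2251468	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
rs838133	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0
rs12780845	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0
rs12134663	0.9	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0
rs957140	0	0	0	0	0.9	0	0	0	0	0	0	0	0	1	0	0	0	0
rs12921383	0	0	0	0.9	0	0	0	0	0	0	0	0	0	0	1	0	0	0
rs7422339	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
rs2851391	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0
rs0cand18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1
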