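# Candidate instruments without usable outcome-GWAS information.
# rs0cand18 is a synthetic placeholder id for the unnamed third candidate.
rs7422339
rs2851391
rs0cand18
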