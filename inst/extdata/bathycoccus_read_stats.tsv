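sample	n_reads	total_bp	mean_length	min_length	max_length	gc_pct	reads_mapped
T142	671249	287619051	429	40	2015	46.7	445046
T149	671832	279858614	417	40	2044	46.5	412383
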