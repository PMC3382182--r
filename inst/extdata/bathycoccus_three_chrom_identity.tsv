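chrom	length_bp	cds_bp	noncds_bp	pct_identical	pct_identical_cds	pct_identical_noncds	pct_ref_t142	pct_ref_t149	pct_t142_t149
chromosome_1	78022	70644	7376	96.7	97.5	89.5	97.8	97.3	98.3
chromosome_2	158544	142659	19681	95.8	97.0	87.2	97.0	96.6	97.4
chromosome_3	123912	115661	12823	96.7	97.4	89.5	97.8	97.4	97.8
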