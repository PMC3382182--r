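chrom	category	length_bp	gc_pct	t142_reads	t142_coverage_bp	t142_coverage_pct	t142_depth	t142_identical_pct	t149_reads	t149_coverage_bp	t149_coverage_pct	t149_depth	t149_identical_pct
chromosome_1	nuclear-standard	1352574	48.87	17507	887310	64.40	4.61	95.50	44115	1260242	90.60	11.26	90.50
chromosome_2	nuclear-standard	1122692	48.55	76131	763755	65.50	23.96	91.70	45448	1045505	89.90	13.84	88.90
chromosome_3	nuclear-standard	1089374	48.62	23634	747266	67.00	7.68	94.50	36961	1032050	91.80	11.66	90.00
chromosome_4	nuclear-standard	1037991	48.29	14217	613146	58.00	4.76	95.70	19099	914632	86.10	6.22	91.90
chromosome_5a	nuclear-standard	550167	48.34	4559	299250	53.40	2.95	96.50	13535	504509	89.20	8.44	90.90
chromosome_5b	nuclear-standard	467783	48.58	2152	222904	47.00	1.58	97.20	13712	437480	90.60	10.02	90.00
chromosome_6	nuclear-standard	989707	48.30	17733	677434	66.90	6.25	94.30	29292	915584	90.10	10.06	90.60
chromosome_7	nuclear-standard	955054	48.42	49892	608532	61.60	17.54	93.30	30116	845293	85.80	10.63	90.30
chromosome_8	nuclear-standard	937610	48.54	10892	545919	57.00	4.09	95.70	29489	841544	86.80	10.70	89.90
chromosome_9	nuclear-standard	895347	48.51	17995	636008	69.30	7.07	93.80	23672	806272	87.50	9.05	90.70
chromosome_10	nuclear-standard	794148	48.38	20350	533074	65.30	9.03	93.70	19996	743420	90.90	8.66	90.20
chromosome_11	nuclear-standard	741502	48.62	26119	516527	67.50	12.50	92.40	12368	634120	83.70	5.70	92.50
chromosome_12a	nuclear-standard	201229	47.52	2066	106614	52.00	3.66	96.30	3707	180588	87.40	6.31	91.40
chromosome_12b	nuclear-standard	511334	48.55	19985	391273	74.20	13.84	92.10	15530	483876	91.70	10.45	89.30
chromosome_13	nuclear-standard	706576	48.54	90889	363302	48.00	45.29	91.30	17849	584838	80.20	8.54	91.00
chromosome_14	nuclear-outlier	662304	42.24	1873	264505	39.30	0.93	97.70	12822	433085	63.70	6.41	93.90
chromosome_15	nuclear-standard	519535	48.13	6320	324598	61.10	4.30	94.80	10865	473213	88.80	7.14	91.60
chromosome_16	nuclear-standard	481036	48.08	14765	268376	52.30	10.67	94.00	14526	445984	87.50	10.16	89.90
chromosome_17	nuclear-standard	465570	47.66	18609	283891	58.50	14.21	91.80	10433	390682	81.30	7.63	90.60
chromosome_18	nuclear-standard	310170	46.97	9003	226193	70.50	10.30	91.20	5203	269409	84.60	5.67	91.00
chromosome_19	nuclear-outlier	146238	41.65	73	10779	7.20	0.13	99.30	129	11504	7.70	0.21	99.10
chloroplast	organelle	54761	41.12	21	5029	6.90	0.09	99.70	46	12675	17.30	0.20	99.40
mitochondrion	organelle	42168	39.97	261	30825	72.20	1.74	97.00	3470	43650	99.90	21.90	91.70
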