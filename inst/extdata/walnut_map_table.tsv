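chrom	snp_markers	genetic_length_cm	n_contigs	n_markers	mtp_length_mb	cen_lo_mb	cen_hi_mb
Jr1	122	79.9	35	1441	63.398	38.4	48.4
Jr2	92	70.5	26	968	48.622	13.2	19.6
Jr3	139	64.3	40	1134	56.126	44.3	46.3
Jr4	112	53.7	35	1000	52.028	43.8	44.8
Jr5	48	45.7	20	478	26.040	12.0	16.9
Jr6	116	60.2	37	1020	56.732	24.4	31.6
Jr7	130	97.3	39	1355	61.010	32.3	34.1
Jr8	78	93.5	18	736	36.629	25.8	31.3
Jr9	56	69.3	19	615	27.927	7.5	11.3
Jr10	135	63.5	55	1253	71.659	34.2	39.5
Jr11	125	66.5	32	1167	54.433	24.0	30.0
Jr12	92	60.5	24	880	42.027	11.0	13.6
Jr13	94	70.0	29	1000	46.491	38.5	40.8
Jr14	85	57.6	18	1033	44.439	27.6	34.6
Jr15	13	37.7	6	203	9.573	NA	NA
Jr16	88	59.3	21	920	38.935	14.7	20.2
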