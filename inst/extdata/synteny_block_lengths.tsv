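comparison	subject_chroms	primary_mb	secondary_mb	tertiary_mb
Jr-Vv	19	600.144	106.351	6.920
Jr-Pt	19	556.891	379.983	62.581
Jr-Md	17	535.223	267.060	6.692
Jr-Mt	8	349.414	133.824	4.715
Jr-Cs	7	459.251	178.461	14.436
Jr-Fv	7	298.298	2.871	0
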