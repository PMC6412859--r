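mirna	mean_log2_ratio	sd_log2	significant	direction	tier
rno-miR-344b-1-3p	-1.95	0.47	TRUE	down	significant
rno-miR-466b-1-3p	-1.10	0.49	TRUE	down	significant
rno-miR-98-5p	-1.07	1.26	FALSE	down	candidate
rno-let-7a-5p	-1.03	1.21	FALSE	down	candidate
rno-miR-1-3p	-0.88	1.19	FALSE	down	candidate
rno-miR-206-3p	-0.86	1.23	FALSE	down	candidate
rno-miR-34b-3p	0.63	0.46	FALSE	up	candidate
rno-miR-181a-2-3p	0.75	0.27	TRUE	up	significant
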