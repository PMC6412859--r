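mirna	mean_log2_change	sd_log2	fold_change	significant	detected	direction
rno-miR-344b-1-3p	NA	NA	NA	FALSE	FALSE	n.d.
rno-miR-466b-1-3p	-3.19	1.59	-9.13	TRUE	TRUE	down
rno-miR-98-5p	-2.45	1.19	-5.48	TRUE	TRUE	down
rno-let-7a-5p	-2.03	0.54	-4.07	TRUE	TRUE	down
rno-miR-1-3p	-2.85	1.03	-7.21	TRUE	TRUE	down
rno-miR-206-3p	-5.19	1.58	-36.42	TRUE	TRUE	down
rno-miR-34b-3p	-2.93	1.76	-7.60	TRUE	TRUE	down
rno-miR-181a-2-3p	3.81	1.55	14.03	TRUE	TRUE	up
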