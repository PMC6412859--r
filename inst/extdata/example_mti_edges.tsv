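mirna	target
rno-miR-466b-1-3p	IGF-1
rno-miR-1-3p	IGF-1
rno-miR-206-3p	IGF-1
rno-miR-466b-1-3p	SLC2a-12
rno-miR-98-5p	SLC2a-12
rno-let-7a-5p	SLC2a-12
rno-miR-1-3p	EIF-4e
rno-miR-206-3p	EIF-4e
rno-miR-34b-3p	EIF-4e
rno-miR-98-5p	ULK-2
rno-let-7a-5p	ULK-2
rno-miR-34b-3p	ULK-2
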