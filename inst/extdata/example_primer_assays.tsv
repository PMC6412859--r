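target	accession	forward_primer	reverse_primer	efficiency	product_size
IGF-1	M15481.1	CAGTTCGTGTGTGGACCAAG	GAGTCTTGGGCATGTCAGTG	1.966	211
SLC2a-12	NM_001107451.1	CCGAGACAAAGGGATGCTCT	CCTTGTAAGTCCTGCCACCA	1.704	251
EIF-4e	NM_053974.2	CAAGCAAACCTTCGGTTGAT	CTCCCCGTTTGTTTTTCTCA	1.743	163
ULK-2	NM_001191645.1	CACAGAACGACCAATGGATG	TTGTTCGAAGGACCATGTGA	2.00	161
GAPDH	NM_017008.4	GCATCTTCTTGTGCAGTGCC	GAGAAGGCAGCCCTGGTAAC	1.991	105
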