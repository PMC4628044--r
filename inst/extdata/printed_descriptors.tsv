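# Single descriptor values printed in the SAR discussion of the source
# report, keyed by compound. These are inputs to the published equations,
# not ground truth for the descriptor engine (geometry/parameter dependent).
compound_id	descriptor	value	citation
7D	R5e+	0.057	SAR discussion, HuCCA-1
8N	R5e+	0.022	SAR discussion, HuCCA-1
21	R5e+	0.023	SAR discussion, HuCCA-1
29	R5e+	0.028	SAR discussion, HuCCA-1
21	MATS7m	-0.020	SAR discussion, HepG2
29	MATS7m	0.040	SAR discussion, HepG2
28	MATS7m	0.064	SAR discussion, HepG2
28	RDF105m	14.609	SAR discussion, HepG2
1P	RDF105m	18.976	SAR discussion, HepG2
19	MATS8v	0.164	SAR discussion, A549
20	MATS8v	0.249	SAR discussion, A549
21	MATS8v	0.348	SAR discussion, A549
8G	MATS8v	0.150	SAR discussion, A549
8B	MATS8v	0.146	SAR discussion, A549
9	Lop	0.740	SAR discussion, MOLT-3
10	Lop	0.740	SAR discussion, MOLT-3
31	Lop	0.876	SAR discussion, MOLT-3
32	Lop	0.876	SAR discussion, MOLT-3
8Q	Lop	0.983	SAR discussion, MOLT-3
8G	Lop	0.983	SAR discussion, MOLT-3
31	R7m	0.377	SAR discussion, MOLT-3
32	R7m	0.385	SAR discussion, MOLT-3
8D	R7m	0.365	SAR discussion, MOLT-3
8M	R7m	0.397	SAR discussion, MOLT-3
8G	R7m	0.519	SAR discussion, MOLT-3
8Q	R7m	0.537	SAR discussion, MOLT-3
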