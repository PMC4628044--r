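# Predicted pIC50 values for structurally modified compounds printed in the
# SAR discussion of the source report (the full modified-compound table is
# in its unavailable supplementary files; only these values are printed).
compound_id	cell_line	pic50	citation
7D	HuCCA-1	-3.915	SAR discussion, HuCCA-1
8N	HuCCA-1	0.054	SAR discussion, HuCCA-1
8A	HuCCA-1	-0.618	SAR discussion, HuCCA-1
8J	HuCCA-1	-1.038	SAR discussion, HuCCA-1
8B	HuCCA-1	-0.786	SAR discussion, HuCCA-1
8K	HuCCA-1	-1.122	SAR discussion, HuCCA-1
8M	HuCCA-1	-0.618	SAR discussion, HuCCA-1
8D	HuCCA-1	-2.466	SAR discussion, HuCCA-1
8E	HuCCA-1	-0.114	SAR discussion, HuCCA-1
8F	HuCCA-1	-0.786	SAR discussion, HuCCA-1
8H	HuCCA-1	-0.702	SAR discussion, HuCCA-1
8R	HuCCA-1	-0.282	SAR discussion, HuCCA-1
1P	HepG2	-0.151	SAR discussion, HepG2
7F	HepG2	-0.163	SAR discussion, HepG2
7P	HepG2	-1.177	SAR discussion, HepG2
8L	A549	-0.779	SAR discussion, A549
8Q	A549	-0.778	SAR discussion, A549
8Q	MOLT-3	0.947	SAR discussion, MOLT-3
8L	MOLT-3	0.110	SAR discussion, MOLT-3
7H	MOLT-3	-1.865	SAR discussion, MOLT-3
8M	MOLT-3	-0.485	SAR discussion, MOLT-3
8D	MOLT-3	-0.818	SAR discussion, MOLT-3
8H	MOLT-3	-0.333	SAR discussion, MOLT-3
8R	MOLT-3	-0.645	SAR discussion, MOLT-3
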