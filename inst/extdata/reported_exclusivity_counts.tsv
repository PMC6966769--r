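category	n_operons	exclusive
NAD biosynthesis	3	2
Heme biosynthesis	5	2
Spermidine biosynthesis	7	3
Sulfur assimilation	11	3
Energy generation	13	1
RISC oxidation	22	7
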