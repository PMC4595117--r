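# units: third-bits
# fitted by coordinate-wise grid search (optimize_structure_matrix) on 10
# simulated families with state-dependent conservation, then selected over
# the competing full-grid optimum by mean Q + mean M on 20 held-out families
H	E	C
4	0	3
0	2	0
3	0	4
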