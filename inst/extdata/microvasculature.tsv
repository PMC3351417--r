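# Microvasculature transcript fold changes (D, D_T1, D_T2 versus N) in the
# STZ-diabetic mouse retina.
gene_symbol	gene_name	d_vs_n	t1_vs_n	t2_vs_n
Edn3	Endothelin 3	1.4	1.5	1.4
VEGFB	Vascular endothelial growth factor B	1.1	1.3 (down)	1.1 (down)
VEGFA	Vascular endothelial growth factor A	1.02	1.4	1.3
Edn2	Endothelin 2	1.4 (down)	1.6 (down)	2.0 (down)
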