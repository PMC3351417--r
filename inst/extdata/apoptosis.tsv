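# Apoptosis-pathway transcript fold changes (D, D_T1, D_T2 versus N) in the
# STZ-diabetic mouse retina.
gene_symbol	gene_name	d_vs_n	t1_vs_n	t2_vs_n
Dapl1	Death associated protein-like 1	2.6	1.2	1.2
Bid	BH3 interacting domain death agonist	1.6	1.5	1.3
Fads3	Fatty acid desaturase 3	1.3	1.2	1.2
Fas	Fas (TNF receptor superfamily member 6)	1.3	1.1	1.2
Bag5	BCL2-associated athanogene 5	1.2	1.2	1.4
Traf3ip3	TRAF3 interacting protein 3	1.5 (down)	1.5 (down)	2.5 (down)
Tnfsf13	Tumor Necrosis Factor superfamily member 13	1.4 (down)	1.5 (down)	1.6 (down)
Tnfrsf18	Tumor necrosis factor receptor superfamily, member 18	1.4 (down)	1.7 (down)	2.2 (down)
Casp7	Caspase 7	1.4 (down)	1.5 (down)	2.0 (down)
Bcl7c	B-cell CLL/lymphoma 7C	1.1 (down)	1.6 (down)	1.3 (down)
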