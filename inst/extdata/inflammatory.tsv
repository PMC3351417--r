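# Inflammatory-pathway transcript fold changes (D, D_T1, D_T2 versus N) in
# the STZ-diabetic mouse retina.
gene_symbol	gene_name	d_vs_n	t1_vs_n	t2_vs_n
C1qtnf5	C1q and tumor necrosis factor related protein 5	2.2	1.9	1.5
CD44	CD44 antigen	1.7	1.3	1.2
Ltbp1	Latent transforming growth factor beta binding protein 1	1.6	1.4	1.4
Islr	Immunoglobulin superfamily containing leucine-rich repeat	1.6	1.5	1.6
Hspb1	Heat shock protein 1	1.6	1.6	1.2
Ifitm1	Interferon induced transmembrane protein 1	1.5	1.4	1.3
Bmp4	Bone morphogenetic protein 4	1.5	1.6	1.5
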