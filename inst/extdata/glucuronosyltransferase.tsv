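# UDP-glucuronosyltransferase transcript fold changes (D, D_T1, D_T2 versus
# N) in the STZ-diabetic mouse retina.
gene_symbol	gene_name	d_vs_n	t1_vs_n	t2_vs_n
Ugt1a5	UDP glucuronosyltransferase 1 family, polypeptide A5	3.3	2	1.5
Ugt1a10	UDP glucuronosyltransferase 1 family, polypeptide A10	3.3	2	1.5
Ugt1a1	UDP glucuronosyltransferase 1 family, polypeptide A1	3.3	2	1.5
Ugt1a9	UDP glucuronosyltransferase 1 family, polypeptide A9	3.3	2	1.5
Ugt1a2	UDP glucuronosyltransferase 1 family, polypeptide A2	3.3	2	1.5
Ugt1a7c	UDP glucuronosyltransferase 1 family, polypeptide A7C	3.3	1.9	1.5
Ugt1a6a	UDP glucuronosyltransferase 1 family, polypeptide A6A	3.3	2	1.5
Ugt1a6b	UDP glucuronosyltransferase 1 family, polypeptide A6B	3.1	2.1	1.5
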