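# Random-coil amide exchange reference factors, version 1 (set "bai1993-spreadsheet").
# log10 multiplicative corrections to the poly-DL-alanine reference rate constants,
# after Bai, Milne, Mayne & Englander (1993) Proteins 17:75-86 as distributed in the
# Englander-laboratory HX spreadsheet; acid factors after Molday, Englander & Kallen
# (1972) Biochemistry 11:150-158 rescaled in the same work.
# lambda = effect of a residue's side chain on its OWN backbone amide;
# rho    = effect of a residue's side chain on the NEXT residue's amide.
# Titrating side chains (Asp, Glu, His) and the C-terminal carboxyl carry separate
# protonated ("_prot") and deprotonated ("_deprot") rows; they are mixed at run time
# according to pD and the pKa values in randomcoil_constants_v1.tsv.
# "NT" = free N-terminal alpha-amino group (rho only, applies to the second residue's
# amide); "CT" = C-terminal carboxyl (lambda only, applies to the last residue's amide).
# Proline rows give the trans-proline rho factors; a proline has no amide hydrogen of
# its own, so its lambda entries are unused.
residue	acid_lambda	acid_rho	base_lambda	base_rho
A	0.00	0.00	0.00	0.00
C	-0.54	-0.46	0.62	0.55
D_deprot	0.90	0.58	0.10	-0.18
D_prot	-0.90	-0.12	0.69	0.60
E_deprot	-0.90	0.31	-0.11	-0.15
E_prot	-0.60	-0.27	0.24	0.39
F	-0.52	-0.43	-0.24	0.06
G	-0.22	0.22	0.27	0.17
H_deprot	0.00	0.00	-0.10	0.14
H_prot	-0.80	-0.51	0.80	0.83
I	-0.91	-0.59	-0.73	-0.23
K	-0.56	-0.29	-0.04	0.12
L	-0.57	-0.13	-0.58	-0.21
M	-0.64	-0.28	-0.01	0.11
N	-0.58	-0.13	0.49	0.32
P	0.00	-0.19	0.00	-0.24
Q	-0.47	-0.27	0.06	0.20
R	-0.59	-0.32	0.08	0.22
S	-0.44	-0.39	0.37	0.30
T	-0.79	-0.47	-0.07	0.20
V	-0.74	-0.30	-0.70	-0.14
W	-0.40	-0.44	-0.41	-0.11
Y	-0.41	-0.37	-0.27	0.05
NT	0.00	-1.32	0.00	1.62
CT_deprot	0.96	0.00	-1.80	0.00
CT_prot	0.05	0.00	0.00	0.00
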