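# Synthetic residue-by-residue composition of the packaged 30-residue
# mucin PTS construct: 18 O-glycans (12 Thr-linked, 6 Ser-linked), one
# neutral histidine, net glycan charge -13 e (10 sialic-acid carboxylates
# + 3 sulfates). The per-site glycan assignment of the original construct
# is not published in machine-readable form; this table is a synthetic
# assignment with the documented counts and total charge, and can be
# replaced via build_mini2_construct(composition_path=).
# glycan column: comma-separated root-to-tip sugar chain, "-" = none.
position	resname	glycan
1	THR	GALNAC,GAL,NEUAC
2	PRO	-
3	THR	GALNAC
4	SER	GALNAC,GAL,NEUAC
5	THR	GALNAC,GALS
6	ALA	-
7	SER	GALNAC,GAL
8	THR	GALNAC,GAL,NEUAC
9	PRO	-
10	THR	GALNAC,GALS
11	SER	GALNAC,GAL,NEUAC
12	THR	GALNAC,GAL,NEUAC,NEUAC
13	GLY	-
14	THR	GALNAC
15	SER	GALNAC,GAL
16	PRO	-
17	THR	GALNAC,GAL,NEUAC
18	THR	GALNAC,GALS
19	SER	GALNAC,GAL,NEUAC
20	ALA	-
21	THR	GALNAC,GAL
22	PRO	-
23	SER	GALNAC,GAL,NEUAC
24	THR	GALNAC
25	GLY	-
26	THR	GALNAC,GAL,NEUAC
27	PRO	-
28	HIS	-
29	THR	-
30	SER	-
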