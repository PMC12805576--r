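# Packaged bead types for the mucin glycopeptide CG model.
# Radii per size class: T 0.191, S 0.230, R 0.264 nm; masses T 36, S 54, R 72 Da.
# charge in elementary charges.
name	size_class	charge	vdw_radius	mass
P2	R	0	0.264	72
SP2	S	0	0.230	54
SP1	S	0	0.230	54
TP1	T	0	0.191	36
SC3	S	0	0.230	54
TC3	T	0	0.191	36
TN6a	T	0	0.191	36
TN5a	T	0	0.191	36
SN6	S	0	0.230	54
SN6d	S	0	0.230	54
TN6d	T	0	0.191	36
SP4r	S	0	0.230	54
SP1r	S	0	0.230	54
TC5	T	0	0.191	36
TC4	T	0	0.191	36
SN4ar	S	0	0.230	54
TN4ar	T	0	0.191	36
Q4n	R	-1	0.264	72
SQ5n	S	-1	0.230	54
TQ5	T	1	0.191	36
TQ5m	T	-1	0.191	36
W	R	0	0.264	72
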