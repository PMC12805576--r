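# N-acetylglucosamine: same bead layout as GalNAc (epimer label only).
residue GLCNAC
hexnac true
ring R1 R2 R3
anomeric R1
anomeric_core C1 C2
anomeric_linked_type TC5
linkage_oxygen O1
acceptor_oxygen O3
bead R1 SN6 C1 C2 O1
bead R2 SP4r C3 C4 O3
bead R3 SP1r C5 C6 O5
bead SD1 TN6a N2 C7
bond R1 R2
bond R2 R3
bond R1 R3
bond R2 SD1
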