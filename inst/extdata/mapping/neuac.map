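# N-acetylneuraminic (sialic) acid: ring plus anionic carboxylate bead
# (SQ5n, charge -1) and N-acetyl arm; donates through its C2 oxygen.
residue NEUAC
ring R1 R2 R3
anomeric R1
anomeric_core C1 C2
anomeric_linked_type TN6d
linkage_oxygen O1
acceptor_oxygen O3
bead R1 SN6 C1 C2 O1
bead R2 SP4r C3 C4 O3
bead R3 SP1r C5 C6 O5
bead SD1 SQ5n C10 O1A O1B
bead SD2 TN6a N2 C7
bond R1 R2
bond R2 R3
bond R1 R3
bond R1 SD1
bond R2 SD2
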