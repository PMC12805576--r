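# 3-O-sulfated galactose: hexose ring plus a Q4n sulfate bead (charge -1)
# on the ring; accepts through O4.
residue GALS
ring R1 R2 R3
anomeric R1
anomeric_core C1 C2
anomeric_linked_type TN6d
linkage_oxygen O1
acceptor_oxygen O4
bead R1 SN6 C1 C2 O1
bead R2 SP4r C3 C4 O4
bead R3 SP1r C5 C6 O5
bead SD1 Q4n S1 O1S O2S O3S
bond R1 R2
bond R2 R3
bond R1 R3
bond R2 SD1
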