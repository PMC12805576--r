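# N-acetylgalactosamine (pseudo-atom ring). Anomeric bead SN6 holds
# C1/C2/O1; on glycosidic donation O1 condenses out and the remaining
# -CH-CH- pair is retyped TC5. Acceptor oxygen O3 sits on ring bead R2.
residue GALNAC
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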