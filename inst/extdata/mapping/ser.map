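# Serine: tiny side bead CB/OG; retyped TN4ar on glycan attachment.
residue SER
backbone BB
linkage_bead SC1
linkage_bead_type TN4ar
acceptor_oxygen OG
bead BB P2 N CA C O
bead SC1 TP1 CB OG
bond BB SC1
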