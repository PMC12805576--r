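# Threonine: side bead holds CB/OG1/CG2; OG1 is the O-glycan acceptor
# oxygen and the side bead is retyped SN4ar on glycan attachment.
residue THR
backbone BB
linkage_bead SC1
linkage_bead_type SN4ar
acceptor_oxygen OG1
bead BB P2 N CA C O
bead SC1 SP1 CB OG1 CG2
bond BB SC1
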