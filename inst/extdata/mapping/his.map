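# Neutral (deprotonated) histidine: three tiny aromatic side beads.
residue HIS
backbone BB
bead BB P2 N CA C O
bead SC1 TC4 CB CG
bead SC2 TN6a ND1 CE1
bead SC3 TN5a CD2 NE2
bond BB SC1
bond SC1 SC2
bond SC1 SC3
bond SC2 SC3
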