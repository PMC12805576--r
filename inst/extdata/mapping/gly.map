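# Glycine: single backbone bead (pseudo-atom mapping).
residue GLY
backbone BB
bead BB P2 N CA C O
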