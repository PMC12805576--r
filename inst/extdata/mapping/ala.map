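# Alanine: backbone + tiny apolar side bead (pseudo-atoms CB/CM).
residue ALA
backbone BB
bead BB P2 N CA C O
bead SC1 TC3 CB CM
bond BB SC1
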