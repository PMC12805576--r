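# Proline: backbone + small apolar ring side bead.
residue PRO
backbone BB
bead BB P2 N CA C O
bead SC1 SC3 CB CG CD
bond BB SC1
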