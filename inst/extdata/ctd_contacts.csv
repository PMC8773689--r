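# Ambiguous NOE contact table for docking the heparin hexasaccharide onto the
# C-terminal domain binding site: 2-O-sulfate terminal oxygens restrained to
# the W59/W74 indole protons, the K68/91 zeta-amine ambiguity pair, and the
# K111 backbone amide proton.
protein_res,protein_atom,ligand_res,ligand_atom
59,HE1,*,O2S*
74,HE1,*,O2S*
68/91,HZ*,*,O2S*
111,H,*,O2S*
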