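# Ambiguous NOE contact table for docking the heparin hexasaccharide onto the
# N-terminal domain binding site: 2-O-sulfate terminal oxygens restrained to
# R52 HE, K49/K54 HZ and W18/W20 HE1, plus the single unambiguous
# K45 HZ - dUA2S H4 contact.
protein_res,protein_atom,ligand_res,ligand_atom
52,HE,*,O2S*
49,HZ*,*,O2S*
54,HZ*,*,O2S*
18,HE1,*,O2S*
20,HE1,*,O2S*
45,HZ*,dUA2S,H4
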