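id,smiles,descriptors
ethyl_acetate,CCOC(C)=O,
methyl_butanoate,CCCC(=O)OC,
ethyl_propanoate,CCOC(=O)CC,
hexanol,CCCCCCO,
butanol,CCCCO,
ethanethiol,CCS,
propanethiol,CCCS,
dimethyl_sulfide,CSC,
acetic_acid,CC(=O)O,
butanoic_acid,CCCC(=O)O,
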