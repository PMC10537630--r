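# Genotoxicity-oriented chemotype definitions (name <TAB> SMARTS).
# Generic structural-alert patterns; bit order of chemotype fingerprints
# follows file order.
nitroso	[NX2]=[OX1]
nitro_aromatic	[c][NX3](=O)=O
nitro_aliphatic	[CX4][NX3](=O)=O
carbamate	[NX3][CX3](=O)[OX2]
sulfonic_ester	[OX2;$(O[CX4])][SX4](=[OX1])(=[OX1])
sulfate_ester	[OX2][SX4](=[OX1])(=[OX1])[OX2]
epoxide	[OX2]1[CX4][CX4]1
aziridine	[NX3]1[CX4][CX4]1
quinone	O=C1C=CC(=O)C=C1
alkyl_halide	[CX4][Cl,Br,I]
aryl_halide	[c][Cl,Br,I]
hydrazine	[NX3][NX3]
azo	[NX2]=[NX2]
azide	[NX2]=[NX2+]=[NX1-]
nitrosamine	[NX3][NX2]=[OX1]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
aldehyde	[CX3H1]=[OX1]
alpha_haloketone	[CX3](=[OX1])[CX4][Cl,Br,I]
isocyanate	[NX2]=[CX2]=[OX1]
aromatic_amine	[c][NX3;H2,H1]
n_oxide	[#7X4+][OX1-]
pah_naphthalene	c1ccc2ccccc2c1
pah_anthracene	c1ccc2cc3ccccc3cc2c1
pah_phenanthrene	c1ccc2c(c1)ccc1ccccc12
acyl_halide	[CX3](=[OX1])[Cl,Br]
thiol	[SX2H]
disulfide	[SX2][SX2]
phosphate_ester	[OX2][PX4](=[OX1])([OX2])[OX2]
benzene_ring	c1ccccc1
carboxylic_acid	[CX3](=O)[OX2H1]
hydroxyl	[OX2H]
ether	[OX2;!$(O=*)]([CX4])[CX4]
tertiary_amine	[NX3]([CX4])([CX4])[CX4]
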