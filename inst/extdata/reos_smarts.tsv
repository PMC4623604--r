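name	smarts
# Default reactive/undesirable substructure set for scaffold filtering.
# The published filter cascade cites external REOS-style pattern
# collections without listing them, so this set is a documented default
# covering the classic electrophile/unstable classes; override via
# filter_config(reactive_smarts = ...).
acyl_halide	[CX3](=O)[F,Cl,Br,I]
aldehyde	[CX3H1](=O)[#6]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
alkyl_halide	[CX4][Cl,Br,I]
peroxide	[OX2][OX2]
epoxide_aziridine	[OX2r3,NX3r3]1[#6r3][#6r3]1
anhydride	[CX3](=O)[OX2][CX3](=O)
isocyanate	[NX2]=[CX2]=[OX1]
isothiocyanate	[NX2]=[CX2]=[SX1]
azide	[NX2]=[NX2+]=[NX1-]
diazo	[NX2]=[NX2]
nitroso	[NX2]=[OX1]
thiol	[SX2H]
sulfonyl_halide	[SX4](=O)(=O)[F,Cl,Br,I]
hydrazine	[NX3][NX3]
imine_of_aldehyde	[CX3H1]=[NX2]
quaternary_ammonium	[NX4+]
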