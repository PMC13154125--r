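# Functional-group substructure patterns (SMARTS), version 1.
# One pattern per line: <group name> <TAB> <SMARTS>.
# Counts are unique substructure matches (symmetry-equivalent atom orderings
# collapse to one match). Patterns are mutually disambiguated:
#   - ester/anhydride oxygens do not count as ether; carboxylic acid is not
#     an ester; the acid OH is not an alcohol; amide/thioamide/nitro
#     nitrogens are not amines; aldehyde and ketone are disjoint via the
#     carbonyl H count; halide counts halogen atoms bonded to carbon.
# Aromatic ring O/S (furan, thiophene) count as ether/thioether.
alcohol	[OX2H][#6;!$([CX3]=[OX1])]
amide	[CX3](=[OX1])[NX3]
imine	[CX3]=[NX2]
nitro	[$([NX3](=[OX1])=[OX1]),$([NX3+](=[OX1])[OX1-])]
nitrile	[CX2]#[NX1]
amine	[NX3;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3](~[OX1])~[OX1]);!$([NX3]#*)]
ether	[OD2;!$([OD2][CX3]=[OX1])]([#6])[#6]
aldehyde	[CX3H1](=[OX1])[#6]
halide	[$([F,Cl,Br,I][#6])]
ketone	[#6][CX3](=[OX1])[#6]
carboxylic_acid	[CX3](=[OX1])[OX2H1]
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
ester	[CX3](=[OX1])[OX2][#6;!$([CX3]=[OX1])]
thiol	[SX2H]
thiocarbonyl	[CX3]=[SX1]
thioether	[SX2;!$([SX2H])]([#6])[#6]
sulfone	[SX4](=[OX1])(=[OX1])
phosphoric_acid	[PX4](=[OX1])([OX2])([OX2])[OX2]
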