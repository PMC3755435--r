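id	name	delta_mass	sites
oxidation	Oxidation	15.994915	M,H,W
carbamidomethyl	Carbamidomethyl	57.021464	C
phospho	Phospho	79.966331	S,T,Y
sulfo	Sulfo	79.956815	S,T,Y
acetyl	Acetyl	42.010565	K,peptide-N
methyl	Methyl	14.015650	K,R
dimethyl	Dimethyl	28.031300	K,R
trimethyl	Trimethyl	42.046950	K
gg	GlyGly (ubiquitin remnant)	114.042927	K
deamidated	Deamidated	0.984016	N,Q
formyl	Formyl	27.994915	K,peptide-N
myristoyl	Myristoyl	210.198366	K,peptide-N
palmitoyl	Palmitoyl	238.229666	C,K
biotin	Biotin	226.077598	K
gln_pyro_glu	Gln to pyro-Glu	-17.026549	Q
glu_pyro_glu	Glu to pyro-Glu	-18.010565	E
dehydrated	Dehydrated	-18.010565	S,T
amidated	Amidated	-0.984016	peptide-C
carbamyl	Carbamyl	43.005814	K,peptide-N
propionamide	Propionamide	71.037114	C
nitro	Nitro	44.985078	Y,W
dioxidation	Dioxidation	31.989829	M,W
cation_na	Sodium adduct	21.981943	D,E,peptide-C
methylthio	Methylthio	45.987721	C
succinyl	Succinyl	100.016044	K
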