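# Curated subset of published pan-assay interference (PAINS) substructure
# families, written as SMARTS from their public descriptions.  Replaceable:
# any tab-separated "smarts<TAB>family" file can be supplied instead.
C=C1C=CC(=O)C=C1	quinone_methide
O=C1C=CC(=O)C=C1	quinone_A
O=C1C(=O)C=CC=C1	ortho_quinone
[OX2H]c1ccccc1[OX2H]	catechol_A
S=C1NC(=O)CS1	rhodanine
O=C1CSC(=S)N1	rhodanine_iso
[OX2H]c1ccccc1C=NN	hzone_phenol
cN=Nc	azo_A
[#6][NX2]=O	nitroso
C=CC(=O)C=C	ene_one_ene
[#6]C(=O)C(=O)[#6]	keto_keto_alpha
O=C1NC(=O)NC(=O)C1=[#6]	alkylidene_barbiturate
NC(=S)N	thiourea
O=C1C=CC(=O)N1	maleimide
O=[N+]([O-])c1ccco1	nitrofuran
[Cl,Br,I][CH2]C(=O)[#6]	alpha_halo_ketone
N#CC=CN	cyano_ene_amine
[SX2H]c1ccccc1	thiophenol
C1(=O)C=CC(=N)C=C1	quinone_imine
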