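# Curated CID fragmentation rules.  One row = one mass-balanced reaction
# template, instantiated per applicable chain (or chain pair) of a precursor.
#
# Part vocabulary (charged / neutrals columns):
#   lcf:<formula>:<label>  fixed-composition class-selective part; label "*"
#                          uses the precursor's lipid class symbol
#   hca:<HCA>:<delta>      one-chain part: HCA reference base + signed delta
#                          (empty delta = the bare base, e.g. an acylium)
#   dbf:<HCA>:<delta>      as hca plus cleavage distal to the last double
#                          bond (loses C_k H_(2k+1), k = carbons - pos - 2)
#   pair:<delta>           two-chain (DAG-type) part, iterated over chain pairs
#   rem                    precursor minus all other parts (exactly one per rule)
# neutrals is ";"-joined.  product_z overrides the product charge (multiply
# charged precursors); label_lcf says whether a head-group isotope label
# transfers onto the lcf part.  ms_level 3 rules chain off the parent rule id.
id	classes	adducts	ms_level	parent	charged	neutrals	product_z	label_lcf	note
pc_neg_nl_head	PC,LPC,PC O-	+CH3COO	2		rem	lcf:C3H6O2:*		FALSE	methyl acetate loss, [M-CH3]-
pc_fmt_nl_head	PC,LPC,PC O-	+HCOO	2		rem	lcf:C2H4O2:*		FALSE	methyl formate loss, [M-CH3]-
pc_neg_carbox	PC,LPC,PC O-	+CH3COO,+HCOO	2		hca:FA:+O	rem		FALSE	FA carboxylate anion
pc_neg_nl_ket	PC,LPC,PC O-	+CH3COO	2		rem	hca:FA:-H;lcf:C3H6O2:*		FALSE	ketene + methyl acetate loss
pc_neg_nl_fa	PC,LPC,PC O-	+CH3COO	2		rem	hca:FA:+HO;lcf:C3H6O2:*		FALSE	fatty acid + methyl acetate loss
pc_fmt_nl_ket	PC,LPC,PC O-	+HCOO	2		rem	hca:FA:-H;lcf:C2H4O2:*		FALSE	ketene + methyl formate loss
pc_fmt_nl_fa	PC,LPC,PC O-	+HCOO	2		rem	hca:FA:+HO;lcf:C2H4O2:*		FALSE	fatty acid + methyl formate loss
pc_pos_lcf184	PC,LPC,PC O-,SM	+H	2		lcf:C5H15NO4P:*	rem		TRUE	phosphocholine head-group cation
pc_pos_nl183	PC,LPC	+H	2		rem	lcf:C5H14NO4P:*		TRUE	phosphocholine neutral loss
pc_pos_nl_ket	PC,LPC	+H	2		rem	hca:FA:-H		FALSE	ketene loss
pc_pos_nl_fa	PC,LPC	+H	2		rem	hca:FA:+HO		FALSE	fatty acid loss
pe_neg_carbox	PE,PE O-,PA	-H	2		hca:FA:+O	rem		FALSE	FA carboxylate anion
pe_neg_nl_fa	PE,PE O-,PA	-H	2		rem	hca:FA:+HO		FALSE	fatty acid loss
pe_neg_nl_ket	PE,PE O-,PA	-H	2		rem	hca:FA:-H		FALSE	ketene loss
pe_neg_lcf140	PE,PE O-	-H	2		lcf:C2H7NO4P:*	rem		TRUE	phosphoethanolamine-derived anion
pe_pos_nl141	PE,PE O-	+H	2		rem	lcf:C2H8NO4P:*		TRUE	phosphoethanolamine loss
pe_pos_nl_ket	PE,PE O-	+H	2		rem	hca:FA:-H		FALSE	ketene loss
ps_neg_lcf153	PS	-H	2		lcf:C3H6O5P:*	rem		FALSE	glycerophosphate anion "PS(153)"
ps_neg_nl87	PS	-H	2		rem	lcf:C3H5NO2:*		TRUE	serine loss "-PS(87)"
ps_neg_carbox	PS	-H	2		hca:FA:+O	rem		FALSE	FA carboxylate anion
ps_neg_decarbox	PS	-H	2		hca:FA:-CO	rem		FALSE	decarboxylated carboxylate
ps_neg_nl_fa	PS	-H	2		rem	hca:FA:+HO;lcf:C3H5NO2:*		TRUE	fatty acid + serine loss
ps_neg_nl_ket	PS	-H	2		rem	hca:FA:-H;lcf:C3H5NO2:*		TRUE	ketene + serine loss
pi_neg_lcf241	PI	-H	2		lcf:C6H10O8P:*	rem		TRUE	dehydrated inositol phosphate anion
pi_neg_lcf153	PI	-H	2		lcf:C3H6O5P:*	rem		FALSE	glycerophosphate anion
pi_neg_carbox	PI	-H	2		hca:FA:+O	rem		FALSE	FA carboxylate anion
pi_neg_nl_fa	PI	-H	2		rem	hca:FA:+HO		FALSE	fatty acid loss
pi_neg_nl_ket	PI	-H	2		rem	hca:FA:-H		FALSE	ketene loss
tag_nh4_nl17	TAG,SE	+NH4	2		rem	lcf:NH3:*		FALSE	ammonia loss
tag_nh4_nl_fa	TAG	+NH4	2		rem	hca:FA:+HO;lcf:NH3:*		FALSE	fatty acid + ammonia loss
tag_nh4_nl_ket	TAG	+NH4	2		rem	hca:FA:-H;lcf:NH3:*		FALSE	ketene + ammonia loss
tag_nh4_acylium	TAG	+NH4	2		hca:FA:	rem		FALSE	acylium cation
tag_nh4_acylium_h2o	TAG	+NH4	2		hca:FA:-HO	rem		FALSE	dehydrated acylium
tag_ms3_acylium	TAG	+NH4	3	tag_nh4_nl_fa	hca:FA:	rem		FALSE	acylium from DAG-type MS2 fragment
tag_ms3_acylium_h2o	TAG	+NH4	3	tag_nh4_nl_fa	hca:FA:-HO	rem		FALSE	dehydrated acylium, MS3
dag_na_nl_fa	DAG	+Na	2		rem	hca:FA:+HO		FALSE	fatty acid loss
dag_na_nl_fana	DAG	+Na	2		rem	hca:FA:+ONa		FALSE	fatty acid sodium salt loss
dag_na_fa_hona	DAG	+Na	2		hca:FA:+HONa	rem		FALSE	sodiated fatty acid cation
dag_na_acylium	DAG	+Na	2		hca:FA:	rem		FALSE	acylium cation
se_nh4_sterol	SE	+NH4	2		hca:ST:-HO	rem		FALSE	dehydrated sterol cation
acar_pos_acylium	ACar	+H	2		hca:FA:	rem		FALSE	acylium cation
acar_pos_mlf2	ACar	+H	2		hca:FA:+C4H6O3	rem		FALSE	acyl + carnitine-derived residue
acar_pos_lcf85	ACar	+H	2		lcf:C4H5O2:*	rem		FALSE	carnitine-derived cation
acoa_neg_mlf	ACoA	-H	2		hca:FA:+C11H20N2O9P2S	rem		FALSE	acyl-pantetheine-phosphate fragment
acoa_neg_nl_ket	ACoA	-H	2		rem	hca:FA:-H		FALSE	ketene loss
cl_2neg_pair	CL	-2H	2		pair:+C6H11O9P2	rem	-1	FALSE	DAG-pair iMLF from doubly charged CL
cl_2neg_carbox	CL	-2H,-H	2		hca:FA:+O	rem	-1	FALSE	FA carboxylate anion
cer_neg_lcb	Cer	-H,+HCOO,+CH3COO	2		hca:LCB:-CH8NO:heavy	rem	-1	FALSE	long-chain-base fragment anion
cer_fmt_nl46	Cer	+HCOO	2		rem	lcf:CH2O2:*		FALSE	formic acid loss, [M-H]-
cer_neg_nl_ket	Cer	-H,+HCOO	2		rem	hca:FA:-H		FALSE	N-acyl ketene loss
dbf_ms3_carbox	PC,PC O-,PE,PE O-,PS,PI	*	3	pc_neg_carbox,pe_neg_carbox,ps_neg_carbox,pi_neg_carbox	dbf:FA:+O	rem		FALSE	cleavage distal to the double bond of a carboxylate
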