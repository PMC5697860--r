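class	category	backbone	slots	rem_classes	adducts_pos	adducts_neg
PC	glycerophospholipid	C8H20NO6P	ester/FA,ester/FA	FA,DAG	+H,+Na	+CH3COO,+HCOO
LPC	glycerophospholipid	C8H20NO6P	ester/FA	FA	+H,+Na	+CH3COO,+HCOO
PC O-	glycerophospholipid	C8H20NO6P	ether/ETH,ester/FA	FA,DAG	+H	+CH3COO,+HCOO
PE	glycerophospholipid	C5H14NO6P	ester/FA,ester/FA	FA,DAG	+H,+Na	-H
PE O-	glycerophospholipid	C5H14NO6P	ether/ETH,ester/FA	FA,DAG	+H	-H
PS	glycerophospholipid	C6H14NO8P	ester/FA,ester/FA	FA,DAG	+H	-H
PI	glycerophospholipid	C9H19O11P	ester/FA,ester/FA	FA,DAG	+H,+NH4	-H
PA	glycerophospholipid	C3H9O6P	ester/FA,ester/FA	FA,DAG	+H,+NH4	-H
CL	glycerophospholipid	C9H22O13P2	ester/FA,ester/FA,ester/FA,ester/FA	FA,DAG,TAG,CL	+H	-H,-2H
DAG	glycerolipid	C3H8O3	ester/FA,ester/FA	FA,DAG	+Na,+NH4,+H
TAG	glycerolipid	C3H8O3	ester/FA,ester/FA,ester/FA	FA,DAG,TAG	+NH4,+Na
SM	sphingolipid	C5H12NO3P	lcb/LCB,amide/FA	FA,Cer	+H	+CH3COO,+HCOO
Cer	sphingolipid		lcb/LCB,amide/FA	FA,Cer	+H	-H,+HCOO,+CH3COO
SE	sterol	 	sterol/ST,ester/FA	FA,SE	+NH4
ACar	fattyacyl	C7H15NO3	ester/FA	FA	+H	-H
ACoA	fattyacyl	C21H36N7O16P3S	ester/FA	FA	+H	-H
FA	fattyacyl	H2O	ester/FA	FA	+H	-H
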