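symbol	delta	z
+H	H	1
+NH4	NH4	1
+Na	Na	1
+Li	Li	1
+K	K	1
-H	-H	-1
-2H	-H2	-2
+HCOO	CHO2	-1
+CH3COO	C2H3O2	-1
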