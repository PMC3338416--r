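kind	name	smiles	tag
scaffold	benzene_13	c1cc({R1})cc({R2})c1	
scaffold	benzene_14	c1cc({R1})ccc1{R2}	
scaffold	pyridine	c1cc({R1})cnc1{R2}	
scaffold	pyrimidine	c1nc({R1})cnc1{R2}	
scaffold	furan	c1oc({R1})cc1{R2}	
scaffold	thiophene	c1sc({R1})cc1{R2}	
scaffold	pyrrole	c1[nH]c({R1})cc1{R2}	
scaffold	oxazole	c1oc({R1})nc1{R2}	
scaffold	thiazole	c1sc({R1})nc1{R2}	
scaffold	isoxazole	c1c({R2})c({R1})on1	
scaffold	pyrazole	c1c({R2})c({R1})[nH]n1	
scaffold	naphthalene	c1ccc2cc({R1})cc({R2})c2c1	
scaffold	quinoline	c1ccc2nc({R1})cc({R2})c2c1	
scaffold	indole	c1cc({R2})c2c(c1)cc({R1})[nH]2	
scaffold	benzimidazole	c1cc({R2})c2c(c1)nc({R1})[nH]2	
scaffold	benzofuran	c1cc({R2})c2c(c1)cc({R1})o2	
scaffold	benzothiophene	c1cc({R2})c2c(c1)cc({R1})s2	
scaffold	biphenyl	c1ccc(-c2ccc({R1})cc2)cc1{R2}	
scaffold	diphenylmethane	C(c1ccc({R2})cc1)c1ccc({R1})cc1	
scaffold	benzodioxole	c1c({R2})c2c(cc1{R1})OCO2	
scaffold	cyclohexane	C1CC({R1})CCC1{R2}	
scaffold	cyclopentane	C1CC({R1})CC1{R2}	
scaffold	piperidine	C1CN({R1})CCC1{R2}	
scaffold	piperazine	C1CN({R1})CCN1{R2}	
scaffold	morpholine	C1COC({R1})CN1{R2}	
scaffold	tetrahydrofuran	C1C({R2})C({R1})OC1	
scaffold	tetrahydrothiophene	C1C({R2})C({R1})SC1	
scaffold	pyrrolidine	C1CC({R1})CN1{R2}	
scaffold	cycloheptane	C1CC({R1})CC({R2})CC1	
scaffold	tetrahydropyran	C1C({R2})C({R1})OCC1	
scaffold	quinoxaline	c1cc({R2})c2nc({R1})cnc2c1	
scaffold	pyridazine	c1cc({R1})nnc1{R2}	
scaffold	pyrimidine_2	c1nc({R1})ncc1{R2}	
scaffold	isoquinoline	c1cc({R2})c2cc({R1})ncc2c1	
scaffold	imidazole	c1[nH]c({R1})nc1{R2}	
scaffold	indane	c1cc({R2})c2c(c1)CC({R1})C2	
scaffold	chromane	c1cc({R2})c2c(c1)CC({R1})CO2	
scaffold	triazole	c1({R2})nc({R1})[nH]n1	
scaffold	tetralin	c1cc({R2})c2c(c1)CCC({R1})C2	
scaffold	oxetane	C1OC({R1})C1{R2}	
substituent	methyl	C	mild
substituent	ethyl	CC	mild
substituent	propyl	CCC	mild
substituent	isopropyl	C(C)C	mild
substituent	butyl	CCCC	polar
substituent	tbutyl	C(C)(C)C	polar
substituent	hydroxy	O	polar
substituent	methoxy	OC	polar
substituent	ethoxy	OCC	polar
substituent	amino	N	polar
substituent	methylamino	NC	polar
substituent	dimethylamino	N(C)C	polar
substituent	fluoro	F	mild
substituent	chloro	Cl	mild
substituent	bromo	Br	mild
substituent	iodo	I	mild
substituent	cyano	C#N	polar
substituent	trifluoromethyl	C(F)(F)F	polar
substituent	trifluoromethoxy	OC(F)(F)F	polar
substituent	formyl	C=O	polar
substituent	acetyl	C(=O)C	polar
substituent	carboxy	C(=O)O	polar
substituent	methylester	C(=O)OC	polar
substituent	carbamoyl	C(=O)N	polar
substituent	methylcarbamoyl	C(=O)NC	polar
substituent	hydroxymethyl	CO	polar
substituent	hydroxyethyl	CCO	polar
substituent	aminomethyl	CN	polar
substituent	aminoethyl	CCN	polar
substituent	methylsulfonyl	S(=O)(=O)C	polar
substituent	sulfamoyl	S(=O)(=O)N	polar
substituent	methylthio	SC	polar
substituent	vinyl	C=C	mild
substituent	ethynyl	C#C	mild
substituent	acetic	CC(=O)O	polar
substituent	glycolate	OCC(=O)O	polar
substituent	acetamido	NC(=O)C	polar
substituent	nitro	[N+](=O)[O-]	polar
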