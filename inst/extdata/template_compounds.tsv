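id	name	synonyms	smiles	formula	chebi	is_generic
C00001	water	H2O|aqua	O	H2O		0
C00002	ATP	adenosine 5'-triphosphate|adenosine triphosphate	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O	C10H16N5O13P3	CHEBI:15422	0
C00008	ADP	adenosine 5'-diphosphate|adenosine diphosphate	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)O)C(O)C1O	C10H15N5O10P2	CHEBI:16761	0
C00020	AMP	adenosine 5'-monophosphate|adenylate|adenosine monophosphate	Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)O)C(O)C1O	C10H14N5O7P	CHEBI:16027	0
C00009	orthophosphate	phosphate|Pi|phosphoric acid	OP(=O)(O)O	H3O4P	CHEBI:18367	0
C00013	diphosphate	pyrophosphate|PPi|diphosphoric acid	OP(=O)(O)OP(=O)(O)O	H4O7P2	CHEBI:29888	0
C00003	NAD	NAD+|nicotinamide adenine dinucleotide	NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O	C21H27N7O14P2	CHEBI:15846	0
C00004	NADH	reduced nicotinamide adenine dinucleotide|dihydronicotinamide adenine dinucleotide	NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O	C21H29N7O14P2	CHEBI:16908	0
C00006	NADP	NADP+|nicotinamide adenine dinucleotide phosphate	NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(OP(=O)(O)O)C2O)C(O)C1O	C21H28N7O17P3	CHEBI:18009	0
C00005	NADPH	reduced nicotinamide adenine dinucleotide phosphate	NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(OP(=O)(O)O)C2O)C(O)C1O	C21H30N7O17P3	CHEBI:16474	0
C00031	glucose	D-glucose|dextrose|grape sugar	OCC1OC(O)C(O)C(O)C1O	C6H12O6	CHEBI:17234	0
C00092	glucose 6-phosphate	D-glucose 6-phosphate|glucose-6-P	OC1C(O)C(OC(O)C1O)COP(=O)(O)O	C6H13O9P	CHEBI:4170	0
C00085	fructose 6-phosphate	D-fructose 6-phosphate|fructose-6-P	OCC1(O)OC(COP(=O)(O)O)C(O)C1O	C6H13O9P	CHEBI:15946	0
C00354	fructose 1,6-bisphosphate	D-fructose 1,6-bisphosphate|fructose bisphosphate	OP(=O)(O)OCC1(O)OC(COP(=O)(O)O)C(O)C1O	C6H14O12P2	CHEBI:16905	0
C00111	dihydroxyacetone phosphate	glycerone phosphate|DHAP	OCC(=O)COP(=O)(O)O	C3H7O6P	CHEBI:16108	0
C00118	glyceraldehyde 3-phosphate	D-glyceraldehyde 3-phosphate|triose phosphate	O=CC(O)COP(=O)(O)O	C3H7O6P	CHEBI:29052	0
C00236	1,3-bisphosphoglycerate	3-phospho-D-glyceroyl phosphate|glycerate 1,3-bisphosphate	O=C(OP(=O)(O)O)C(O)COP(=O)(O)O	C3H8O10P2	CHEBI:16001	0
C00197	3-phosphoglycerate	3-phospho-D-glycerate|glycerate 3-phosphate|3-phosphoglyceric acid	OC(=O)C(O)COP(=O)(O)O	C3H7O7P	CHEBI:17794	0
C00631	2-phosphoglycerate	2-phospho-D-glycerate|glycerate 2-phosphate|2-phosphoglyceric acid	OC(=O)C(OP(=O)(O)O)CO	C3H7O7P	CHEBI:17835	0
C00074	phosphoenolpyruvate	PEP|phosphoenolpyruvic acid	OC(=O)C(=C)OP(=O)(O)O	C3H5O6P	CHEBI:18021	0
C00022	pyruvate	pyruvic acid|2-oxopropanoate|2-oxopropanoic acid|pyroracemic acid	CC(=O)C(=O)O	C3H4O3	CHEBI:15361	0
C00186	lactate	L-lactate|lactic acid|2-hydroxypropanoate	CC(O)C(=O)O	C3H6O3	CHEBI:16651	0
C00033	acetate	acetic acid|ethanoate	CC(=O)O	C2H4O2	CHEBI:30089	0
C00011	CO2	carbon dioxide|carbonic anhydride	O=C=O	CO2	CHEBI:16526	0
C00007	oxygen	O2|dioxygen	O=O	O2	CHEBI:15379	0
C00027	hydrogen peroxide	H2O2|peroxide	OO	H2O2	CHEBI:16240	0
C00025	glutamate	L-glutamate|glutamic acid|2-aminoglutarate	NC(CCC(=O)O)C(=O)O	C5H9NO4	CHEBI:16015	0
C00064	glutamine	L-glutamine|2-amino-4-carbamoylbutanoate	NC(CCC(N)=O)C(=O)O	C5H10N2O3	CHEBI:18050	0
C00049	aspartate	L-aspartate|aspartic acid|2-aminosuccinate	NC(CC(=O)O)C(=O)O	C4H7NO4	CHEBI:17053	0
C00041	alanine	L-alanine|2-aminopropanoate	CC(N)C(=O)O	C3H7NO2	CHEBI:16977	0
C00014	ammonia	NH3|azane	N	H3N	CHEBI:16134	0
C00044	GTP	guanosine 5'-triphosphate|guanosine triphosphate	Nc1nc2c(ncn2C2OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C2O)c(=O)[nH]1	C10H16N5O14P3	CHEBI:15996	0
C00035	GDP	guanosine 5'-diphosphate|guanosine diphosphate	Nc1nc2c(ncn2C2OC(COP(=O)(O)OP(=O)(O)O)C(O)C2O)c(=O)[nH]1	C10H15N5O11P2	CHEBI:17552	0
C00089	sucrose	saccharose|cane sugar	OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O	C12H22O11	CHEBI:17992	0
C02591	sucrose 6-phosphate	sucrose 6'-phosphate|sucrose-6-P	OP(=O)(O)OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O	C12H23O14P	CHEBI:91002	0
C01182	ribulose 1,5-bisphosphate	D-ribulose 1,5-bisphosphate|RuBP	OP(=O)(O)OCC(=O)C(O)C(O)COP(=O)(O)O	C5H12O11P2	CHEBI:16710	0
C00158	citrate	citric acid|2-hydroxypropane-1,2,3-tricarboxylate	OC(=O)CC(O)(CC(=O)O)C(=O)O	C6H8O7	CHEBI:30769	0
C00417	cis-aconitate	cis-aconitic acid|prop-1-ene-1,2,3-tricarboxylate	OC(=O)C=C(CC(=O)O)C(=O)O	C6H6O6	CHEBI:32805	0
C00311	isocitrate	isocitric acid|1-hydroxypropane-1,2,3-tricarboxylate	OC(=O)C(O)C(CC(=O)O)C(=O)O	C6H8O7	CHEBI:30887	0
C00026	2-oxoglutarate	alpha-ketoglutarate|2-oxoglutaric acid|2-oxopentanedioate	OC(=O)CCC(=O)C(=O)O	C5H6O5	CHEBI:16810	0
C05379	oxalosuccinate	oxalosuccinic acid|1-oxalosuccinate	OC(=O)C(=O)C(CC(=O)O)C(=O)O	C6H6O7	CHEBI:16971	0
C00042	succinate	succinic acid|butanedioate	OC(=O)CCC(=O)O	C4H6O4	CHEBI:30031	0
C00122	fumarate	fumaric acid|trans-butenedioate	OC(=O)C=CC(=O)O	C4H4O4	CHEBI:18012	0
C00149	malate	L-malate|malic acid|2-hydroxysuccinate	OC(=O)CC(O)C(=O)O	C4H6O5	CHEBI:15589	0
C00036	oxaloacetate	oxaloacetic acid|2-oxosuccinate|oxalacetic acid	OC(=O)CC(=O)C(=O)O	C4H4O5	CHEBI:16452	0
C00048	glyoxylate	glyoxylic acid|oxoacetate	O=CC(=O)O	C2H2O3	CHEBI:36655	0
C05993	acetyl adenylate	acetyl-AMP|acetyl adenosine monophosphate	CC(=O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc23)C(O)C1O	C12H16N5O8P	CHEBI:16027x	0
C00542	cystathionine	L-cystathionine|2-amino-4-(2-amino-2-carboxyethyl)sulfanylbutanoate	NC(CCSCC(N)C(=O)O)C(=O)O	C7H14N2O4S	CHEBI:17482	0
C05330	homocysteine	L-homocysteine|2-amino-4-sulfanylbutanoate	NC(CCS)C(=O)O	C4H9NO2S	CHEBI:17588	0
C00010	CoA	coenzyme A|CoA-SH		C21H36N7O16P3S	CHEBI:15346	0
C00024	acetyl-CoA	acetyl coenzyme A|acetyl-S-CoA		C23H38N7O17P3S	CHEBI:15351	0
C00091	succinyl-CoA	succinyl coenzyme A|succinyl-S-CoA		C25H40N7O19P3S	CHEBI:15380	0
C00068	thiamine diphosphate	thiamin diphosphate|ThPP|thiamine pyrophosphate		C12H18N4O7P2S	CHEBI:18290	0
C05125	3-carboxy-1-hydroxypropyl-ThPP	2-(3-carboxy-1-hydroxypropyl)thiamine diphosphate		C16H24N4O10P2S		0
C15972	lipoamide-E	enzyme N6-(lipoyl)lysine|lipoyllysine		C8H15NOS2		0
C15973	dihydrolipoamide-E	enzyme N6-(dihydrolipoyl)lysine|dihydrolipoyllysine		C8H17NOS2		0
C16254	succinyldihydrolipoamide-E	enzyme N6-(S-succinyldihydrolipoyl)lysine		C12H21NO4S2		0
C17569	ubiquinone-8	ubiquinone 8|coenzyme Q8		C49H74O4		0
C17570	ubiquinol-8	ubiquinol 8|reduced coenzyme Q8		C49H76O4		0
C00080	H+	proton|hydron		H		0
C00069	an alcohol	alcohols|a primary alcohol				1
C00071	an aldehyde	aldehydes				1
C00399	ubiquinone	a ubiquinone|quinone cofactor				1
C00390	ubiquinol	a ubiquinol|quinol cofactor				1
C62101	a sphingoid base	sphingoid bases				1
C62102	a 3-oxo sphingoid base	3-oxo sphingoid bases				1
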