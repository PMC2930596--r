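id	equation	ec	pathway
R00299	1 C00031 + 1 C00002 = 1 C00092 + 1 C00008	2.7.1.1	glycolysis
R00771	1 C00092 = 1 C00085	5.3.1.9	glycolysis
R00756	1 C00085 + 1 C00002 = 1 C00354 + 1 C00008	2.7.1.11	glycolysis
R01068	1 C00354 = 1 C00111 + 1 C00118	4.1.2.13	glycolysis
R01015	1 C00111 = 1 C00118	5.3.1.1	glycolysis
R01061	1 C00118 + 1 C00003 + 1 C00009 = 1 C00236 + 1 C00004	1.2.1.12	glycolysis
R01512	1 C00236 + 1 C00008 = 1 C00197 + 1 C00002	2.7.2.3	glycolysis
R01518	1 C00197 = 1 C00631	5.4.2.11	glycolysis
R00658	1 C00631 = 1 C00074 + 1 C00001	4.2.1.11	glycolysis
R00200	1 C00074 + 1 C00008 = 1 C00022 + 1 C00002	2.7.1.40	glycolysis
R00703	1 C00022 + 1 C00004 = 1 C00186 + 1 C00003	1.1.1.27	pyruvate metabolism
R00351	1 C00036 + 1 C00024 + 1 C00001 = 1 C00158 + 1 C00010	2.3.3.1	tca
R01325	1 C00158 = 1 C00417 + 1 C00001	4.2.1.3	tca
R01900	1 C00417 + 1 C00001 = 1 C00311	4.2.1.3	tca
R00709	1 C00311 + 1 C00003 = 1 C00026 + 1 C00011 + 1 C00004	1.1.1.41	tca
R00267	1 C00311 + 1 C00006 = 1 C00026 + 1 C00011 + 1 C00005	1.1.1.42	tca
R08549	1 C00026 + 1 C00010 + 1 C00003 = 1 C00091 + 1 C00011 + 1 C00004	1.2.1.52	tca
R00405	1 C00091 + 1 C00008 + 1 C00009 = 1 C00042 + 1 C00002 + 1 C00010	6.2.1.5	tca
R00412	1 C00042 + 1 C17569 = 1 C00122 + 1 C17570	1.3.5.1	tca
R01082	1 C00122 + 1 C00001 = 1 C00149	4.2.1.2	tca
R00342	1 C00149 + 1 C00003 = 1 C00036 + 1 C00004	1.1.1.37	tca
R00343	1 C00149 + 1 C00006 = 1 C00036 + 1 C00005	1.1.1.82	tca
R00479	1 C00311 = 1 C00042 + 1 C00048	4.1.3.1	glyoxylate
R00472	1 C00048 + 1 C00024 + 1 C00001 = 1 C00149 + 1 C00010	2.3.3.9	glyoxylate
R00253	1 C00025 + 1 C00014 + 1 C00002 = 1 C00064 + 1 C00008 + 1 C00009	6.3.1.2	nitrogen
R00248	1 C00026 + 1 C00014 + 1 C00005 = 1 C00025 + 1 C00006 + 1 C00001	1.4.1.4	nitrogen
R00355	1 C00049 + 1 C00026 = 1 C00036 + 1 C00025	2.6.1.1	amino acids
R00258	1 C00041 + 1 C00026 = 1 C00022 + 1 C00025	2.6.1.2	amino acids
R00803	1 C02591 + 1 C00001 = 1 C00089 + 1 C00009	3.1.3.24	sucrose
R00024	1 C01182 + 1 C00011 + 1 C00001 = 2 C00197	4.1.1.39	calvin
R00235	1 C00033 + 1 C00002 = 1 C05993 + 1 C00013	6.2.1.1	acetate
R00236	1 C05993 + 1 C00010 = 1 C00024 + 1 C00020	6.2.1.1	acetate
R01286	1 C00542 + 1 C00001 = 1 C05330 + 1 C00022 + 1 C00014	4.4.1.8	sulfur
R03316	1 C00026 + 1 C00068 = 1 C05125 + 1 C00011	1.2.4.2	tca
R02570	1 C05125 + 1 C15972 = 1 C16254 + 1 C00068	1.2.4.2	tca
R02571	1 C16254 + 1 C00010 = 1 C00091 + 1 C15973	2.3.1.61	tca
R00432	1 C00091 + 1 C00035 + 1 C00009 = 1 C00042 + 1 C00044 + 1 C00010	6.2.1.4	tca
R01195	1 C00074 + 1 C00035 = 1 C00022 + 1 C00044	2.7.1.40	glycolysis
R00009	2 C00027 = 2 C00001 + 1 C00007	1.11.1.6	detox
R01324	1 C00311 + 1 C00006 = 1 C05379 + 1 C00005	1.1.1.42	tca
R01323	1 C05379 + 1 C00006 = 1 C00026 + 1 C00011 + 1 C00005	1.1.1.42	tca
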