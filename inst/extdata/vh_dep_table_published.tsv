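accession	log2fc	q_mod	description	n_peptides	id_fdr	direction
P01011	1.316	0.030	Alpha-1-antichymotrypsin	31	0.01	up
A0A1B0GWE8	1.439	0.046	Cathepsin D	29	0.01	up
P10523	4.277	0.000	S-arrestin	27	0.01	up
P36222	2.538	0.008	Chitinase-3-like protein	126	0.01	up
B4DPQ0	1.341	0.033	Complement subcomponent C1r	25	0.01	up
P02788	2.487	0.029	Lactotransferrin	22	0.01	up
Q17R60	3.535	0.000	Interphotoreceptor matrix proteoglycan	122	0.01	up
A0A7I2V2D2	1.431	0.032	Plasma protease C1 inhibitor	20	0.01	up
P62873	3.122	0.016	Guanine nucleotide-binding protein G(I)/G(S)/G(T) subunit beta-	119	0.01	up
P02042	3.110	0.019	Hemoglobin subunit delta	15	0.01	up
P08571	1.418	0.012	Monocyte differentiation antigen CD	1415	0.01	up
P07858	1.488	0.025	Cathepsin B	12	0.01	up
P69905	3.407	0.048	Hemoglobin subunit alpha	12	0.01	up
Q9BZV3	3.479	0.004	Interphotoreceptor matrix proteoglycan	212	0.01	up
P01033	1.686	0.020	Metalloproteinase inhibitor	111	0.01	up
Q6EMK4	2.422	0.005	Vasorin	11	0.01	up
P07602	1.946	0.016	Prosaposin	10	0.01	up
Q92743	1.469	0.044	Serine protease HTRA	110	0.01	up
P08779	1.364	0.048	Keratin, type I cytoskeletal	169	0.01	up
P61769	1.301	0.046	Beta-2-microglobulin	9	0.01	up
P63211	5.403	0.000	Guanine nucleotide-binding protein G(T) subunit gamma-T	17	0.01	up
Q96JP9	2.445	0.005	Cadherin-related family member	16	0.01	up
D6RHI9	1.484	0.038	Ribonuclease T2 (Fragment)	5	0.01	up
P07205	2.584	0.032	Phosphoglycerate kinase	25	0.01	up
P55058	2.086	0.002	Phospholipid transfer protein	5	0.01	up
Q8N114	3.579	0.001	Protein shisa-	54	0.01	up
Q9HCQ7	2.668	0.008	Pro-FMRFamide-related neuropeptide VF	4	0.01	up
B3KRD8	3.275	0.046	Section 14-like 2 (S. cerevisiae), isoform CRA_c	3	0.01	up
E9PEK4	2.488	0.004	Receptor protein-tyrosine kinase	3	0.01	up
O95897	2.549	0.008	Noelin-	23	0.01	up
P29279	1.957	0.002	CCN family member	23	0.01	up
Q14974	3.193	0.016	Importin subunit beta-	13	0.01	up
Q8NBJ4	1.542	0.004	Golgi membrane protein	13	0.01	up
A0A7P0T9A7	3.187	0.032	Adenylosuccinate lyase	2	0.01	up
B0QYH5	3.626	0.001	Seizure 6-like protein	2	0.01	up
H0YBL1	3.495	0.009	Inositol-1-monophosphatase (Fragment)	2	0.01	up
P17936	1.198	0.032	Insulin-like growth factor-binding protein	32	0.01	up
P30740	4.397	0.009	Leukocyte elastase inhibitor	2	0.01	up
Q9NP84	2.029	0.012	Tumor necrosis factor receptor superfamily member 12 A	2	0.01	up
Q9UHI8	1.696	0.029	A disintegrin and metalloproteinase with thrombospondin motifs	12	0.01	up
A0A2R8YFQ7	1.507	0.021	Lambda-crystallin homolog	1	0.05	up
A0A8Q3WKS4	1.206	0.040	Lactadherin	1	0.01	up
E9PK73	5.529	0.001	Succinate dehydrogenase [ubiquinone] cytochrome b small subunit	1	0.05	up
P00352	-3.349	0.033	Aldehyde dehydrogenase 1A	142	0.01	down
P53674	-3.459	0.045	Beta-crystallin B	142	0.01	down
P48637	-3.230	0.026	Glutathione synthetase	31	0.01	down
P05813	-3.819	0.048	Beta-crystallin A	327	0.01	down
P29401	-3.434	0.035	Transketolase	25	0.01	down
Q00796	-3.047	0.032	Sorbitol dehydrogenase	18	0.01	down
P53672	-4.549	0.001	Beta-crystallin A	217	0.01	down
P04792	-3.898	0.010	Heat shock protein beta-	111	0.01	down
Q5TDP6	-3.195	0.048	Lengsin	10	0.01	down
Q93088	-3.076	0.029	Betaine–homocysteine S-methyltransferase	18	0.01	down
Q96GW7	-2.168	0.013	Brevican core protein	8	0.01	down
P15121	-3.143	0.013	Aldo-keto reductase family 1 member B	17	0.01	down
P30041	-3.447	0.000	Peroxiredoxin-	67	0.01	down
P00390	-2.319	0.029	Glutathione reductase, mitochondrial	6	0.01	down
P07900	-2.578	0.028	Heat shock protein HSP 90-alpha	6	0.01	down
P0DOX3	-3.374	0.001	Immunoglobulin delta heavy chain	5	0.01	down
P22061	-2.093	0.046	Protein-L-isoaspartate(D-aspartate) O-methyltransferase	5	0.01	down
P38606	-2.371	0.020	V-type proton ATPase catalytic subunit A	4	0.01	down
P13798	-2.618	0.006	Acylamino-acid-releasing enzyme	3	0.01	down
P40227	-3.349	0.001	T-complex protein 1 subunit zeta	3	0.01	down
E9PQW4	-1.622	0.025	Mitogen-activated protein kinase	2	0.01	down
O75347	-1.741	0.005	Tubulin-specific chaperone A	2	0.01	down
P07737	-2.689	0.004	Profilin-	12	0.01	down
P13489	-2.265	0.001	Ribonuclease inhibitor	2	0.01	down
Q14764	-3.119	0.001	Major vault protein	2	0.01	down
Q96C23	-1.999	0.012	Galactose mutarotase	2	0.01	down
A0A0A0MS98	-3.022	0.001	Band 3 anion transport protein	1	0.05	down
B1AK87	-1.412	0.048	F-actin-capping protein subunit beta	1	0.05	down
D6RA82	-5.612	0.000	Annexin	1	0.05	down
D6RAY0	-2.175	0.002	Alcohol dehydrogenase class-	31	0.01	down
E9PLN1	-2.688	0.033	UPF0686 protein C11orf	11	0.05	down
H0Y8C6	-2.046	0.048	Importin-5 (Fragment)	1	0.01	down
O00515	-3.770	0.001	Ladinin-	11	0.05	down
P01601	-1.796	0.015	Immunoglobulin kappa variable 1D-	161	0.05	down
P26447	-2.418	0.001	Protein S100-A	41	0.05	down
P49773	-2.017	0.034	Adenosine 5'-monophosphoramidase HINT	11	0.05	down
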