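# P. priestleyi BC1401 genes sharing the HlyD domain of alg44 while lacking
# a PilZ domain, as annotated in the deposited IMG/ER draft-genome
# annotation (gene ids, products, Pfam domain labels). Coordinates are
# synthetic placeholders: gene ids encode only contig membership and
# within-contig order, which is all the alg44-like scan needs.
gene_id	contig	start	end	strand	product	length_aa	domains
Ga0079976_1001251	Ga0079976_1001	251001	252398	+	HlyD family secretion protein	466	pfam13533;Biotin_lipoyl_2;pfam16576;HlyD_D23
Ga0079976_100279	Ga0079976_1002	79001	80185	+	HlyD family secretion protein	395	pfam13437;HlyD_3;pfam13533;Biotin_lipoyl_2
Ga0079976_100288	Ga0079976_1002	88001	89431	+	HlyD family secretion protein	477	pfam13437;HlyD_3;pfam13533;Biotin_lipoyl_2
Ga0079976_100319	Ga0079976_1003	19001	20452	+	RND family efflux transporter, MFP subunit	484	pfam16576;HlyD_D23
Ga0079976_100646	Ga0079976_1006	46001	47155	+	HlyD family secretion protein	385	pfam13437;HlyD_3;pfam13533;Biotin_lipoyl_2
Ga0079976_10149	Ga0079976_1014	9001	10389	+	membrane fusion protein, multidrug efflux system	463	pfam13533;Biotin_lipoyl_2;pfam16576;HlyD_D23
Ga0079976_101677	Ga0079976_1016	77001	78440	+	RND family efflux transporter, MFP subunit	480	pfam16576;HlyD_D23
Ga0079976_101876	Ga0079976_1018	76001	77314	+	HlyD family secretion protein	438	pfam13533;Biotin_lipoyl_2;pfam16576;HlyD_D23
Ga0079976_102849	Ga0079976_1028	49001	50668	+	membrane fusion protein, multidrug efflux system	556	pfam16576;HlyD_D23
Ga0079976_103537	Ga0079976_1035	37001	38302	+	HlyD family secretion protein	434	pfam13437;HlyD_3;pfam13533;Biotin_lipoyl_2
Ga0079976_103615	Ga0079976_1036	15001	16314	+	RND family efflux transporter, MFP subunit	438	pfam13533;Biotin_lipoyl_2;pfam16576;HlyD_D23
Ga0079976_104331	Ga0079976_1043	31001	32527	+	HlyD family secretion protein	509	pfam13437;HlyD_3;pfam13533;Biotin_lipoyl_2
Ga0079976_106912	Ga0079976_1069	12001	13329	+	RND family efflux transporter, MFP subunit	443	pfam13437;HlyD_3;pfam13533;Biotin_lipoyl_2
Ga0079976_10868	Ga0079976_1086	8001	9590	+	membrane fusion protein, cobalt-zinc-cadmium efflux	530	pfam16576;HlyD_D23
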