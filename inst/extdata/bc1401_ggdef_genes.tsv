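# P. priestleyi BC1401 genes carrying GGDEF/GGEEF Pfam domains, from the
# deposited IMG/ER draft-genome annotation. The motif column records whether
# the literal GGDEF/GGEEF motif is present in the gene product
# (Ga0079976_10297 carries the domain but not the motif). Coordinates are
# synthetic placeholders.
gene_id	contig	start	end	strand	product	length_aa	domains	motif
Ga0079976_102110	Ga0079976_1021	10001	10995	+	Response regulator receiver modulated diguanylate cyclase	331	pfam00990;GGDEF	present
Ga0079976_106215	Ga0079976_1062	15001	15938	+	Response regulator receiver modulated diguanylate cyclase	312	pfam00990;GGDEF	present
Ga0079976_102431	Ga0079976_1024	31001	32787	+	Response regulator receiver modulated diguanylate cyclase/phosphodiesterase	595	pfam00990;GGDEF	present
Ga0079976_101496	Ga0079976_1014	96001	97841	+	Response regulator receiver modulated diguanylate cyclase/phosphodiesterase	613	pfam00990;GGDEF	present
Ga0079976_10199	Ga0079976_1019	9001	11177	+	PAS domain S-box-containing protein/diguanylate cyclase (GGDEF) domain-containing protein	725	pfam00990;GGDEF	present
Ga0079976_10297	Ga0079976_1029	7001	8592	+	Diguanylate cyclase (GGDEF) domain-containing protein	530	pfam00990;GGDEF	absent
Ga0079976_101051	Ga0079976_1010	51001	53198	+	PAS domain S-box-containing protein/diguanylate cyclase (GGDEF) domain-containing protein	732	pfam00990;GGDEF	present
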