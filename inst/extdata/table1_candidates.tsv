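kingdom	phylum	species	protein	accession	trimmed
Fungi	Chytridiomycota	Spizellomyces punctatus	SpunGRL1	XP_016607089.1	FALSE
Fungi	Chytridiomycota	Spizellomyces palustris	SpalGRL1	TPX68946.1	FALSE
Protista	Amoebozoa	Protostelium aurantium var. fungivorum	PfunGRL1	PRP89608.1	FALSE
Protista	Apusozoa	Thecamonas trahens	TtraGRL1	XP_013761079.1	FALSE
Protista	Apusozoa	Thecamonas trahens	TtraGRL2	XP_013753662.1	FALSE
Protista	Apusozoa	Thecamonas trahens	TtraGRL3	XP_013759733.1	TRUE
Protista	Apusozoa	Thecamonas trahens	TtraGRL4	XP_013759396.1	FALSE
Protista	Apusozoa	Thecamonas trahens	TtraGRL5	XP_013757274.1	FALSE
Protista	Apusozoa	Thecamonas trahens	TtraGRL6	XP_013755387.1	FALSE
Protista	Chromerida	Vitrella brassicaformis	VbraGRL1	CEM13019.1	FALSE
Protista	Chromerida	Vitrella brassicaformis	VbraGRL2	CEL93132.1	FALSE
Protista	Chromerida	Vitrella brassicaformis	VbraGRL3	CEM19221.1	FALSE
Protista	Chromerida	Vitrella brassicaformis	VbraGRL4	CEM01650.1	FALSE
Protista	Chromerida	Vitrella brassicaformis	VbraGRL5	CEM10760.1	FALSE
Protista	Chromerida	Vitrella brassicaformis	VbraGRL6	CEM25255.1	FALSE
Plantae	Chlorophyta	Chloropicon primus	CpriGRL1	QDZ19318.1	FALSE
Plantae	Chlorophyta	Micromonas pusilla	MpusGRL1	XP_003054778.1	FALSE
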