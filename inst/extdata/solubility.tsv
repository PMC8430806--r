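phase	category	g_per_L	note
Sylvite	soluble	347	water solubility from source dataset
Arcanite	soluble	111.5	water solubility from source dataset
Fairchildite	reactive		decomposes in water to buetschliite, then to calcite plus water-soluble K2CO3
Halite	soluble	360	common reference value, not from the source dataset
Mg-Sulphate	soluble	351	common reference value, not from the source dataset
Hydroxylapatite	insoluble		apatites require HNO3 or acids with pH below 5.5
Chlorapatite	insoluble		apatites require HNO3 or acids with pH below 5.5
Fluorapatite	insoluble		apatites require HNO3 or acids with pH below 5.5
Calcite	insoluble		no solubility in water
Ankerite	insoluble		no solubility in water
Wollastonite	insoluble		insoluble in water
Periclase	insoluble		insoluble in water
Huntite	insoluble		carbonate, standard reference
Quartz	insoluble		standard reference
Cristobalite low	insoluble		standard reference
Ilmenite	insoluble		standard reference
Rutile	insoluble		standard reference
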