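phase	formula	wtpct	esd
Amorphous		34	0.8
Hydroxylapatite	Ca_5_(PO_4_)_3_OH	6.26	0.18
Chlorapatite	Ca_5_(PO_4_)_3_Cl	1.66	0.18
Fluorapatite	Ca_5_(PO_4_)_3_F	0.25	0.04
Na-Al-Phosphate	NaAl(P_2_O_7_)	0.1	0.1
Calcite	CaCO_3_	13.56	0.15
Fairchildite	K_2_Ca(CO_3_)_2_	7.25	0.1
Ankerite	CaFe_0.6_Mg_0.3_Mn_0.1_(CO_3_)_2_	1.77	0.16
Sylvite	KCl	14.11	0.14
Arcanite	K_2_(SO_4_)	6.81	0.12
Periclase	MgO	7.77	0.12
Wollastonite	CaSiO_3_	3.54	0.15
Quartz	SiO_2_	0.39	0.04
Huntite	CaMg_3_(CO_3_)_4_	1.4	0.2
Mg-Sulphate	MgSO_4_	0.2	0.05
Halite	NaCl	0.49	0.05
Ilmenite	FeTiO_3_	0.2	0.05
Cristobalite low	SiO_2_	0.04	0.02
Rutile	TiO_2_	0.25	0.06
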