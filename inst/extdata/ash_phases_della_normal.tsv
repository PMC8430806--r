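phase	formula	wtpct	esd
Amorphous		31.2	1
Hydroxylapatite	Ca_5_(PO_4_)_3_OH	4	0.2
Chlorapatite	Ca_5_(PO_4_)_3_Cl	5.4	0.3
Fluorapatite	Ca_5_(PO_4_)_3_F	0.22	0.05
Na-Al-Phosphate	NaAl(P_2_O_7_)	0.3	0.12
Calcite	CaCO_3_	5.03	0.15
Fairchildite	K_2_Ca(CO_3_)_2_	15.87	0.17
Ankerite	CaFe_0.6_Mg_0.3_Mn_0.1_(CO_3_)_2_	2.33	0.17
Sylvite	KCl	16.4	0.2
Arcanite	K_2_(SO_4_)	5.79	0.13
Periclase	MgO	7.1	0.13
Wollastonite	CaSiO_3_	3.39	0.14
Quartz	SiO_2_	0.38	0.06
Huntite	CaMg_3_(CO_3_)_4_	1.2	0.2
Mg-Sulphate	MgSO_4_	0.2	0.06
Halite	NaCl	0.44	0.06
Ilmenite	FeTiO_3_	0.23	0.05
Cristobalite low	SiO_2_	0.042	0.02
Rutile	TiO_2_	0.37	0.07
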