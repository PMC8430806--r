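phase	formula	wtpct	esd
Amorphous		31.8	0.9
Hydroxylapatite	Ca_5_(PO_4_)_3_OH	5.6	0.2
Chlorapatite	Ca_5_(PO_4_)_3_Cl	2.12	0.18
Fluorapatite	Ca_5_(PO_4_)_3_F	0.22	0.05
Na-Al-Phosphate	NaAl(P_2_O_7_)	1.3	0.2
Calcite	CaCO_3_	25.5	0.2
Fairchildite	K_2_Ca(CO_3_)_2_	2.43	0.11
Ankerite	CaFe_0.6_Mg_0.3_Mn_0.1_(CO_3_)_2_	3	0.2
Sylvite	KCl	8.61	0.11
Arcanite	K_2_(SO_4_)	4.7	0.16
Periclase	MgO	4.45	0.11
Wollastonite	CaSiO_3_	6.1	0.2
Quartz	SiO_2_	1.16	0.05
Huntite	CaMg_3_(CO_3_)_4_	0.28	0.11
Mg-Sulphate	MgSO_4_	0.83	0.09
Halite	NaCl	0.61	0.05
Ilmenite	FeTiO_3_	0.63	0.08
Cristobalite low	SiO_2_	0.17	0.04
Rutile	TiO_2_	0.49	0.06
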