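phase	formula	wtpct	esd
Amorphous		27.4	0.8
Hydroxylapatite	Ca_5_(PO_4_)_3_OH	6.9	0.19
Chlorapatite	Ca_5_(PO_4_)_3_Cl	1.69	0.19
Fluorapatite	Ca_5_(PO_4_)_3_F	0.31	0.05
Na-Al-Phosphate	NaAl(P_2_O_7_)	0.3	0.11
Calcite	CaCO_3_	14.7	0.14
Fairchildite	K_2_Ca(CO_3_)_2_	5.18	0.1
Ankerite	CaFe_0.6_Mg_0.3_Mn_0.1_(CO_3_)_2_	1.82	0.15
Sylvite	KCl	18.35	0.16
Arcanite	K_2_(SO_4_)	10.53	0.12
Periclase	MgO	7.57	0.11
Wollastonite	CaSiO_3_	2.26	0.13
Quartz	SiO_2_	0.71	0.04
Huntite	CaMg_3_(CO_3_)_4_	1.3	0.2
Mg-Sulphate	MgSO_4_	0.13	0.04
Halite	NaCl	0.37	0.05
Ilmenite	FeTiO_3_	0.29	0.05
Cristobalite low	SiO_2_	0.03	0.02
Rutile	TiO_2_	0.16	0.06
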