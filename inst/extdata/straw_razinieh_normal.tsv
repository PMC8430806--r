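element	value	sd	unit	flag
Ash	6.46	0.24	%	
C	43.10	0.52	%	
H	5.63	0.1	%	
N	1.76	0.02	%	
S	0.29	0.05	%	
Cl	1.01		%	single
Na	76.00	0.58	mg/kg	
Mg	3580	10	mg/kg	
Al	98.00	1.73	mg/kg	
Si	1600	10	mg/kg	
P	1710	5.77	mg/kg	
K	16100	100	mg/kg	
Ca	9720	20.8	mg/kg	
Ti	7.00	0.58	mg/kg	
Fe	109	3.46	mg/kg	
Zn	54.00	0	mg/kg	
Pb	<4.00		mg/kg	
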