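element	value	sd	unit	flag
Ash	3.47	0.04	%	
C	44.40	0.52	%	
H	5.78	0.04	%	
N	0.99	0.02	%	
S	0.19	0.05	%	
Cl	0.51		%	single
Na	14.00	3.06	mg/kg	
Mg	1900	17.3	mg/kg	
Al	34.00	0.71	mg/kg	
Si	1580	14.1	mg/kg	
P	772	16	mg/kg	
K	7990	92.4	mg/kg	
Ca	5050	78.1	mg/kg	
Ti	<4.00		mg/kg	
Fe	44.0	1	mg/kg	
Zn	37.00	0.58	mg/kg	
Pb	<4.00		mg/kg	
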