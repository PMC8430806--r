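element	value	sd	unit	flag
Ash	4.11	0.17	%	
C	43.90	0.36	%	
H	5.77	0.08	%	
N	1.11	0.01	%	
S	0.17	0.05	%	
Cl	0.61		%	single
Na	23.00	0.58	mg/kg	
Mg	1850	10	mg/kg	
Al	41.00	4.04	mg/kg	
Si	707	10.4	mg/kg	
P	924	7.23	mg/kg	
K	13000	57.7	mg/kg	
Ca	4720	17.3	mg/kg	
Ti	<4.00		mg/kg	
Fe	55	0.71	mg/kg	
Zn	44.00	1	mg/kg	
Pb	<4.00		mg/kg	
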