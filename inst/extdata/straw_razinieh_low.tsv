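element	value	sd	unit	flag
Ash	5.93	0.15	%	
C	43.20	0.39	%	
H	5.76	0.03	%	
N	1.25	0.07	%	
S	0.18	0.03	%	
Cl	0.53		%	single
Na	30.0	3.21	mg/kg	
Mg	2530	15.3	mg/kg	
Al	125.00	0.71	mg/kg	
Si	3890	14.1	mg/kg	
P	1300	5.77	mg/kg	
K	9210	68.1	mg/kg	
Ca	11000	57.7	mg/kg	
Ti	7.00	0.58	mg/kg	
Fe	96.00	1.73	mg/kg	
Zn	78.00	0.71	mg/kg	
Pb	<4.00		mg/kg	
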