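element	value	sd	flag
C	4.17	0.03	
S	1.59	0.24	
Cl	9.62		single
Mg	4.50	0.02	
Si	1.68	0.02	
P	2.24	0.03	
K	32.70	0.4	
Ca	11.70	0.01	
Fe	0.13	0	
Zn	<0.20		
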