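element	value	sd	flag
C	4.61	0.04	
S	1.11	0.16	
Cl	10.90		single
Mg	4.23	0.01	
Si	6.54	0.04	
P	2.12	0	
K	15.80	0.07	
Ca	18.90	0.08	
Fe	0.16	0	
Zn	<0.20		
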