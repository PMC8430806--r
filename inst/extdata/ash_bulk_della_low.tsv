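element	value	sd	flag
C	4.09	0.16	
S	1.48	0.17	
Cl	8.25		single
Mg	5.55	0	
Si	4.44	0	
P	2.20	0	
K	24.20	0	
Ca	14.90	0.01	
Fe	0.13	0	
Zn	<0.20		
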