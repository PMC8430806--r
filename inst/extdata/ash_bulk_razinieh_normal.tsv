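element	value	sd	flag
C	3.36	0.07	
S	2.16	0.28	
Cl	10.70		single
Mg	5.49	0.01	
Si	2.14	0.02	
P	2.63	0	
K	25.60	0.08	
Ca	14.70	0.01	
Fe	0.16	0	
Zn	<0.20		
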