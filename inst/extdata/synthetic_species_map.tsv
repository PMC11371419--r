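species	ecomorph	region
sp01	trawler	Nr
sp02	gleaner	WP
sp03	aerial_hawker	EP
sp04	trawler	Af
sp05	gleaner	Nt
sp06	aerial_hawker	IM
sp07	trawler	Oc
sp08	gleaner	Nr
sp09	aerial_hawker	WP
sp10	trawler	EP
sp11	gleaner	Af
sp12	aerial_hawker	Nt
sp13	trawler	IM
sp14	gleaner	Oc
sp15	aerial_hawker	Nr
sp16	trawler	WP
sp17	gleaner	EP
sp18	aerial_hawker	Af
sp19	trawler	Nt
sp20	gleaner	IM
sp21	aerial_hawker	Oc
sp22	trawler	Nr
sp23	outgroup	OG
sp24	outgroup	OG
sp25	outgroup	OG
sp26	outgroup	OG
sp27	outgroup	OG
sp28	outgroup	OG
sp29	outgroup	OG
sp30	outgroup	OG
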