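collection	strain_id	habitat	location	ploidy
EXF-9	1	brine	Ebre Delta salterns, Spain	1
EXF-12	2	brine	Santa Pola salterns, Spain	1
EXF-15	3	brine	Santa Pola salterns, Spain	1
EXF-20	4	brine	Santa Pola salterns, Spain	2
EXF-152	5	brine	Secovlje salterns, Slovenia	2
EXF-153, EXF-2781	6	brine	Secovlje salterns, Slovenia	2
EXF-154	7	brine	Secovlje salterns, Slovenia	2
EXF-156, CBS 116.90	8	eye infection of aquarium Spondyliosoma cantharus	unknown	2
EXF-157, CBS 115.90	9	kidney of Bufo granulosus	Brazil	1
EXF-161, EXF-2689, CBS 706.76	10	leaf of Rhizophora mangle	Senegal	2
EXF-166, CBS 100496	11	seawater-sprayed marble	Delos, Greece	2
EXF-177, CBS 705.76	12	Tinea nigra	France	1
EXF-241	13	brine	Secovlje salterns, Slovenia	2
EXF-269, EXF-108	14	brine	Santa Pola salterns, Spain	2
EXF-291	15	brine	Secovlje salterns, Slovenia	2
EXF-561	16	brine	Namibia, salterns at the Atlantic coast	1
EXF-2515	17	brine	salterns, Puerto Rico	1
EXF-2516	18	brine	salterns, Puerto Rico	1
EXF-2683, CBS 117.90	19	salted fish, Osteoglossum bicirrhosum	Brazil	2
EXF-2685	20	brine	Secovlje salterns, Slovenia	1
EXF-2783	21	brine	Secovlje salterns, Slovenia	1
EXF-2785	22	brine	Secovlje salterns, Slovenia	2
EXF-3845	23	brine	Candelaria salterns, Puerto Rico	1
EXF-3846	24	brine	Candelaria salterns, Puerto Rico	1
EXF-4716	25	brine bait	Secovlje salterns, Slovenia	2
EXF-6274	26	brine	Secovlje salterns, Slovenia	2
EXF-6652	27	spider web in a cave close to the ocean	Atacama, Chile	2
EXF-6663	28	spider web in a cave close to the ocean	Atacama, Chile	1
EXF-8170	29	brine	Secovlje salterns, Slovenia	2
EXF-8422	30	biofilm from cheese factory brine	Celje, Slovenia	2
EXF-10304	31	brine	Secovlje salterns, Slovenia	2
EXF-10508	32	seawater, depth 25 m	Italy	2
EXF-10509	33	seawater, depth 200 m	Italy	2
EXF-10510	34	seawater, depth 94 m	Italy	2
EXF-10511	35	seawater, depth 25 m	Italy	2
EXF-10512	36	seawater, depth 25 m	Italy	4
EXF-10816	37	bittern after halite precipitation	Secovlje salterns, Slovenia	2
EXF-10819	38	bittern after halite precipitation	Secovlje salterns, Slovenia	2
EXF-10820	39	bittern after halite precipitation	Secovlje salterns, Slovenia	1
EXF-10843	40	brine	Secovlje salterns, Slovenia	2
EXF-10904	41	bittern after halite precipitation	Secovlje salterns, Slovenia	2
EXF-10907	42	bittern after halite precipitation	Secovlje salterns, Slovenia	2
EXF-10919	43	bittern after halite precipitation	Secovlje salterns, Slovenia	2
EXF-10958	44	bittern after halite precipitation	Secovlje salterns, Slovenia	1
EXF-10974	45	brine	Secovlje salterns, Slovenia	2
EXF-11540	46	sand in a cave close to the ocean	Atacama, Chile	2
EXF-11650	47	sand in a cave close to the ocean	Atacama, Chile	2
EXF-11651	48	sand in a cave close to the ocean	Atacama, Chile	1
EXF-12619	49	coral or deep sea	China	1
EXF-12620	50	coral or deep sea	China	2
EXF-14591, CMF-020	51	plankton tow	Vineyard Sound, USA	2
EXF-14592, AMF 061	52	plankton tow	Vineyard Sound, USA	1
EXF-225	53	malt extract medium, 25% NaCl (w/v)	long-term experimental evolution	2
EXF-14590, MSW 12-1B	54	marine	List on Sylt, Germany	2
EXF-2000	A	brine	Secovlje salterns, Slovenia	2
EXF-120	B	brine	Santa Pola saltpans, Spain	2
EXF-562	C	soil on the sea coast	Namibia	1
EXF-2788	D	brine	Secovlje salterns, Slovenia	1
EXF-171	E	keratomycosis	Brazil	2
EXF-2682	F	Trichomycosis nigra	Italy	2
EXF-10513	G	deep seawater	Italy	2
EXF-151	H	Tinea nigra	Portugal	2
EXF-6651	I	spider web in a cave close to the ocean	Atacama, Chile	2
EXF-6669	J	spider web in a cave close to the ocean	Atacama, Chile	2
EXF-6654	K	spider web in a cave close to the ocean	Atacama, Chile	2
EXF-6656	L	rock wall in a cave close to the ocean	Atacama, Chile	2
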