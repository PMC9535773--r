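collection	strain_id	habitat	location	ploidy
EXF-924	1	ponds on sea ice	Svalbard, Norway	1
EXF-926	2	surface glacial ice	Svalbard, Norway	2(?)
EXF-3233	3	deep sea (4,500 m b.s.l.)	Japan	1
EXF-3371	4	soil	Thailand	1
EXF-3378	5	public fountain	Thailand	1
EXF-3397	6	endoperitoneal fluid	Greece	2
EXF-4450	8	Iskra factory	Slovenia	2
EXF-5590	9	dishwasher rubber seal	Slovenia	2
EXF-6171	10	glacial ice	Argentina	2
EXF-7932	11	metal drain on the kitchen sink	Sweden	1
EXF-7946	12	kitchen metal holder for washed dishes	Sweden	1
EXF-8016	13	bathroom faucet and sink contact	Sweden	1
EXF-8022	14	refrigerator inner surface	Sweden	1
EXF-8044	15	kitchen metal holder for washed dishes	Sweden	1
EXF-8258	16	well water	Slovenia	2
EXF-9877	17	tap water	Slovenia	2
EXF-11403	18	refrigerator inner surface	Sweden	2(?)
EXF-8492	19	well water	Slovenia	2
EXF-8678	20	well water	Slovenia	2
EXF-8689	21	well water	Slovenia	2
EXF-8695	22	well water	Slovenia	2
EXF-8702	23	well water	Slovenia	2
EXF-8986	24	fango mud from Secovlje salterns	Slovenia	2
EXF-9262	25	rubber on kitchen drain	Slovenia	1
EXF-9470	26	kitchen counter above dishwasher	Slovenia	2
EXF-9272	27	kitchen strainer basket	Slovenia	1
EXF-9298	28	plastic mesh on kitchen drain	Slovenia	2
EXF-9304	29	kitchen strainer basket	Slovenia	2
EXF-9313	30	kitchen sink	Slovenia	2
EXF-9454	31	tap water	Slovenia	2
EXF-9484	32	kitchen counter above dishwasher	Slovenia	2
EXF-9887	33	tap water	Slovenia	2
EXF-9516	34	kitchen sink drain	Slovenia	2
EXF-9539	35	kitchen strainer basket	Slovenia	1
EXF-9540	36	dishwasher door	Slovenia	2
EXF-10064	37	tap water	Slovenia	2
EXF-11060	38	ceiling surface	Slovenia	2(?)
EXF-9875	39	tap water	Slovenia	2
EXF-9906	40	Arthrocnemum sp. plant surface from Secovlje saltern	Slovenia	1
EXF-9911	41	kitchen sink drain	Slovenia	2
EXF-9937	42	kitchen sink drain	Slovenia	2
EXF-10061	43	tap water	Slovenia	2
EXF-10062	44	tap water	Slovenia	2
EXF-10066	45	tap water	Slovenia	2
EXF-10333	46	tap water	Slovenia	2
EXF-10372	47	air in the National Gallery restoration center	Slovenia	1
EXF-10726	48	integument of a male alate ant of Atta sexdens rubropilosa	Brazil	1
EXF-11028	49	water from the aquarium with Proteus anguinus	Slovenia	2
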