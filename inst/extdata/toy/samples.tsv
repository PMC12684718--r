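sample_id	latitude	longitude	glacier_area	distance_to_glacier	water_temperature	chlorophyll_a	glacier_index
s001	61.8262441564734	-149.103658586694	335530.35226099	3115.90695529885	4.88094839316182	1.01247558742332	0.156759199671355
s002	27.2307459728787	84.7038931577654	20419.5807167878	3426.86557747794	7.77796661899692	2.25278568631623	0.0400298594966541
s003	-42.4896619946755	169.831299397986	21016.3351404608	1834.50828982713	6.56515089497626	3.34261634674079	0.0732365240836955
s004	44.5489557565034	41.9027319346384	1207122.80432486	938.011868386725	2.54965051352554	0.325494296176295	0.539445985846781
s005	27.5913243709442	84.117773268942	545492.982340956	2234.7548489547	5.36620273418706	0.958795464373107	0.248399946508416
s006	25.9835054379331	81.2799697248013	22855.3848426641	4742.9803791874	4.97033277928684	2.18161967036477	0.0308898695720061
s007	-28.1472583119958	-71.4654359754099	1156002.7532343	3060.2916730879	4.06546928102051	0.294495056290172	0.259988918245515
s008	-43.1206262707832	169.238423984626	3085914.92622337	599.205234269492	2.10607986386613	0.351713337512322	0.745655718923166
s009	62.3169945394689	-147.612299255418	390192.714463576	1344.95527597833	5.61332424871012	1.23341512230277	0.317146176861596
s010	-44.9982841713754	168.446839247056	1082347.54897834	1343.48038835101	1.86898627936165	1.1481660392617	0.436421679543739
s011	45.9539159992416	7.764140784088	1229201.19056462	645.884243745061	2.38517407572213	0.104495281031804	0.631886212858136
s012	-40.8570283842619	171.238802572282	1949189.21271746	627.889963303118	3.1643756162684	0.132232105140868	0.689781307746733
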