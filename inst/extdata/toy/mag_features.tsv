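mag_id	completeness	contamination	genome_size	gene_count	trna_count	gc_content	coding_density	domain	phylum	class	order	family	genus
mag_001	0.962643909663893	0.0910836397670209	4153680.49700161	3818.06559668875	48.0613038158536	0.579162043647375	0.874442998544343	Bacteria	p001	c001	o001	f001	g001
mag_002	0.811083423788659	0.0926343811908737	3418820.34667135	3229.94280826452	30.0506473169953	0.499775656219572	0.898423664122183	Bacteria	p001	c001	o001	f002	g002
mag_003	0.700727647263557	0.0282592382980511	2798879.60472338	2555.20940695257	32.3298694438103	0.559549543180037	0.922106313668655	Bacteria	p001	c001	o001	f002	g002
mag_004	0.731133008771576	0.0558731271885335	3421991.02991645	3236.05135622822	33.0551989624835	0.497749833541457	0.907061516819091	Bacteria	p001	c001	o001	f002	g002
mag_005	0.808605061611161	0.083570246398449	3368639.80205011	3078.07992842226	30.0979193168703	0.524063403299078	0.933039780118096	Bacteria	p001	c001	o001	f002	g002
mag_006	0.868854625010863	0.0541692910483107	3715571.54145901	3318.34368789817	40.0148683392693	0.619892526650801	0.910139413861893	Bacteria	p001	c001	o001	f002	g002
mag_007	0.715413552639075	0.0935846921987832	3418571.9204819	3129.07839889865	33.4986737418511	0.675069216941483	0.887897667406979	Bacteria	p001	c001	o001	f003	g003
mag_008	0.799986060801893	0.0347154604038224	3243640.28660062	2884.1783127949	38.3445521384925	0.666820455668494	0.911847504339476	Bacteria	p001	c001	o001	f004	g004
mag_009	0.812446674052626	0.0445405797800049	2934459.24260657	2676.63222026458	41.4718126440953	0.442005335108843	0.900206117429227	Bacteria	p001	c001	o001	f004	g004
mag_010	0.852853532182053	0.0220092140836641	3470986.16047548	3124.04202498598	37.0041123266077	0.577830856631044	0.905894680557646	Bacteria	p001	c001	o001	f004	g005
mag_011	0.874523015972227	0.0111766204703599	3486806.14041624	3202.23142524081	52.4249806020818	0.541583227808587	0.919191894576196	Bacteria	p001	c001	o002	f005	g006
mag_012	0.89170678507071	0.0433483144734055	3955579.62607947	3605.73260630852	40.2410099799538	0.606525803776458	0.925016957193854	Bacteria	p002	c002	o003	f006	g007
mag_013	0.888997981394641	0.0401036527240649	3207522.36856587	2827.83263904865	43.3661686524243	0.378104642673861	0.913796019540428	Bacteria	p002	c002	o003	f006	g007
mag_014	0.866613226220943	0.0066452659200877	3598905.14525188	3396.0118675497	34.8107515899881	0.565178781014401	0.867214827514453	Bacteria	p002	c002	o003	f006	g007
mag_015	0.792507000640035	0.0530521711334586	3225080.66517012	3024.76575121079	36.9383629109024	0.698467934108339	0.887798230049365	Bacteria	p002	c002	o004	f007	g008
mag_016	0.844369457522407	0.0528976865811273	3703026.74296136	3490.71957466103	35.3387408318687	0.559767862700391	0.903613519877252	Bacteria	p002	c002	o004	f007	g008
mag_017	0.787573567358777	0.0825100514572114	3365015.57735166	3087.7410913614	40.9533924366573	0.471207659563515	0.90292208192427	Bacteria	p002	c002	o004	f007	g008
mag_018	0.856217581219971	0.0786259391577914	3765973.25657571	3436.38244074478	41.464196878829	0.539631677977741	0.888980743001746	Bacteria	p002	c002	o004	f007	g008
mag_019	0.836358734290116	0.00530055989511311	3758767.31870885	3563.37368010151	44.3650341368751	0.442126824904699	0.875300973521886	Bacteria	p002	c002	o004	f007	g009
mag_020	0.701443911762908	0.0891314275097102	3259273.06832102	2888.81883149525	24.7519214936054	0.374270141660236	0.908964053854482	Bacteria	p002	c003	o005	f008	g010
mag_021	0.804077161778696	0.0787987691117451	4448334.57302231	4100.00409760335	36.250448648809	0.599320584780071	0.906725855508658	Bacteria	p003	c004	o006	f009	g011
mag_022	0.994069016864523	0.0696838264353573	5365222.11363361	4846.54844213909	60.0477752054667	0.670159039250575	0.890374738058551	Bacteria	p003	c004	o006	f009	g011
mag_023	0.964054980291985	0.0772758572595194	5181884.16842429	4755.4728791807	40.5748094267556	0.605912674730644	0.89883878151822	Bacteria	p003	c004	o006	f010	g012
mag_024	0.969666420621797	0.00180417711380869	4790642.94381745	4394.19440790775	39.0114631304991	0.370433971146122	0.9122064865112	Bacteria	p003	c004	o006	f010	g012
mag_025	0.983799254358746	0.00044996845535934	5181940.2595401	4719.36788934439	48.6645736574026	0.551889625086915	0.890817335668508	Bacteria	p003	c004	o007	f011	g013
mag_026	0.748427773686126	0.0446740072686225	3835722.13134965	3531.07475464653	45.5586815875801	0.625497911497951	0.912007148325971	Bacteria	p003	c004	o007	f011	g013
mag_027	0.836100913165137	0.0548062907066196	4391671.0584431	4041.0950462444	37.1348778344611	0.582625752163585	0.909890978585709	Bacteria	p003	c004	o007	f012	g014
mag_028	0.879717928939499	0.0236531302798539	4527498.79574561	4222.00135952701	41.6840583466423	0.688654276204761	0.915520042587858	Bacteria	p003	c004	o007	f013	g015
mag_029	0.91085220540408	0.0940404888475314	5095755.16631561	4605.04400202847	46.5602060041024	0.6702019672608	0.884280488328689	Bacteria	p003	c004	o007	f014	g016
mag_030	0.855522690084763	0.00280681625008583	4108678.4334258	3805.560709845	45.5294477807945	0.690500210470054	0.921661933772714	Bacteria	p003	c004	o007	f014	g016
mag_031	0.937001371360384	0.0447313215350732	2745227.9851873	2358.71535280733	31.3266758127203	0.532925373315811	0.882851148029247	Bacteria	p003	c005	o008	f015	g017
mag_032	0.955216951412149	0.072745469561778	3096508.24897193	2911.87218105839	47.7140724227788	0.376844920497388	0.902504383102163	Bacteria	p003	c005	o008	f015	g017
mag_033	0.790898181777447	0.0451933208154514	2308951.35346808	2232.93384887205	37.8793796201761	0.681331865722314	0.87550941037375	Bacteria	p003	c005	o008	f016	g018
mag_034	0.84381023007445	0.0610217343783006	2803645.95781967	2614.18432407028	35.2319525535343	0.669024872931186	0.891263582813564	Bacteria	p003	c005	o008	f016	g019
mag_035	0.707523141778074	0.0556530659319833	2397965.36534092	2252.87112010706	38.5278387832345	0.699091204104479	0.903319538606439	Bacteria	p003	c005	o008	f016	g019
mag_036	0.930643705069087	0.0274726891424507	3022075.59281139	2765.26799612308	38.4194279277983	0.646323510771617	0.879092347798091	Bacteria	p003	c005	o008	f016	g019
mag_037	0.893065303121693	0.0353648962220177	2647363.9474432	2346.07233997958	40.0185096751573	0.582733571482822	0.888364989687489	Bacteria	p003	c005	o008	f016	g019
mag_038	0.903595818323083	0.0559138944139704	3253806.06758781	2856.77518142776	39.9762384729208	0.42270138770109	0.913987818935194	Bacteria	p003	c005	o009	f017	g020
mag_039	0.916714811837301	0.0974724034545943	2294960.10968534	2056.37610777434	48.2108068601623	0.574369915539864	0.905290399083402	Bacteria	p003	c005	o009	f017	g021
mag_040	0.813717678538524	0.0214580245316029	2457346.73902664	2230.79906298443	49.8882842727654	0.543298371741548	0.896955602712548	Bacteria	p003	c005	o010	f018	g022
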