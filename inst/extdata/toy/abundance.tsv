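mag_id	s001	s002	s003	s004	s005	s006	s007	s008	s009	s010	s011	s012
mag_001	1.8424023338585	0	16.5468954552318	0.534152265625064	0	0.292941437525582	0	0.623403026176295	0	0	3.5004948420838	0
mag_002	4.38195143268238	3.61938149979978	0.481831189292556	3.04324719083421	0.377107083391259	18.1359150127818	17.3938491630548	0.894609105195358	1.19553276325634	12.5066756020225	12.5555213873019	26.7516369257614
mag_003	0	0.497453189439068	5.72828984075471	1.11096105030476	4.23947121691854	0.328823889860618	1.83810433274275	0	0.260544685640157	2.36790705395122	0	0
mag_004	4.87236317369603	3.70074150079925	1.05359048478016	0.335763065283695	1.3590083940125	0	1.21644902183482	0	4.98783965784174	0	0.390779028270169	4.00284814370664
mag_005	16.5207137896442	0	0.388882613544166	0.708158199997312	21.7982681171368	6.69534507372711	0	9.72949930203537	0.638239553517098	0.80467222522342	7.78027103067449	9.08588903731889
mag_006	0.973254881325527	6.89675320251706	0	16.718052404766	0.275043513575034	0	0	19.7005957326759	40.7658144948948	1.13111952919744	0	6.28057094553071
mag_007	0	0	6.33295711872289	0.576434314921358	0.522151704067114	0.418768687736124	7.8443151530531	25.1202896488346	1.51225753410531	7.28238558009478	2.09726101550637	1.41018532399866
mag_008	4.43759103570621	2.12726083515829	0	0.98541906938833	4.09134343443719	0.885934048463437	6.51651723823993	20.0244324261972	2.55504915937098	5.43237281103389	0.766396578162468	0
mag_009	2.06608170023002	0.576960444090427	0.442766726092404	4.50007398464482	4.36719814856497	0.334220923080272	0.493540406771813	79.6412213827258	0	7.70712117561004	30.3969149876719	0.291543913162783
mag_010	0	0	0	0	0	0	0	0	0	11.9491874133218	0	1.13483703076055
mag_011	0.811677854430071	2.9582827656542	6.34585505214699	0	3.78286374162719	2.90882920439576	0	0	0.959741463741314	0	4.07243180474145	8.71431476590069
mag_012	4.5805663996678	0.352045342420696	0	0	0	0	5.04700409622932	0	3.10053939499043	0	0	3.692711483674
mag_013	1.01312879251638	2.49141681781995	0.479961317433949	1.29280624822183	0	1.82586123623009	1.72025645299899	19.3372923289902	0.311003809664971	2.20768673545331	1.96138038767926	0
mag_014	3.7007616634723	0	0.23283393030481	1.79361154273901	1.1232623760505	0.977013444386865	0.229434708916205	0	0.810432076488105	0	5.0857553637004	0
mag_015	4.70601908677449	1.08990657600182	17.7471691706799	1.6564242455542	1.19230805114408	1.76204610329087	0.577394741678409	0	7.15207836323342	4.38044838654497	6.24223764103357	3.04618033245183
mag_016	8.42525927524532	31.7680652082322	57.2441772316878	151.315650439866	39.0061455121194	3.46637927354696	107.42617824632	2.45410597660525	33.7192547319253	0.408438066002107	0.905031717100894	38.6487797813469
mag_017	2.06987914035427	0.614865893354142	2.61588703326664	0	0.546853927498055	0.244977446116074	0.731732051713153	3.52242948049907	0.243461823142448	12.8983174036942	22.7331771859801	1.55703019993625
mag_018	0	0.250233189227341	33.6378224637153	7.56445291476318	0	0	2.920469240173	3.67728652061621	0	48.1586901588834	0	1.99806926530062
mag_019	0	0	0	2.06600664938662	0	0.799765712045836	0.393460032751948	0	0.632896712934975	0	0	0
mag_020	20.5229190735005	0.558416698598083	0.878755729943163	0	3.8241800454628	5.8520116666593	0.548600080235889	0.765428920622274	0.308821953631383	1.51501215030734	0.916636035795132	0
mag_021	0	0	1.17316212141968	0	0.683665998765797	9.00771210550833	0.674599783748665	0.339412831298842	1.73642641728389	5.46809182529425	0.296794942195844	0
mag_022	0.395950953197547	5.20881801049815	3.6109597167865	81.0712307212685	2.36627337747764	0.442492959522835	2.21098061061704	0.523183020812596	8.70484670261369	15.292723708364	0	0
mag_023	3.87626004595829	0	0	3.82909288662143	1.69316345174947	0	0	0.292338988850569	0.514776810698875	0	0	0.73348637217166
mag_024	38.0927863600588	0	3.33071329899084	2.8559478328712	0	0.377587644616659	0	1.2667679341866	11.0189661154661	44.0860534533496	22.7429133701166	0.750461865679895
mag_025	171.038234696098	4.06977324284775	7.86866508317234	23.7601293709488	7.95039175468968	31.1461715162843	2.41826403548211	6.64148727254325	4.37656449352565	15.0655637111833	0	0.641192971509093
mag_026	1.03433261913064	1.80008710537011	2.28237543787966	12.7926618222951	0.643690060796796	0.481304972166104	0.937358326499176	1.56206459468191	2.54818539889286	0.670553128767173	15.3219142443605	36.5516083247242
mag_027	0	31.3150467585112	3.27203407534726	0.393540223868397	0.325234268837788	4.47480699972101	41.4476350823207	0	0.417508555959419	10.825567691241	6.03929592390925	6.80013809266405
mag_028	0	0	0	0	0.248379473242547	1.58169380153038	0.817158684055995	0	0	1.3709216286321	0.259178282856072	17.6882086980457
mag_029	0.392782394833199	0.262464583380247	3.08767521889881	3.23924708360234	1.32743444357376	0	20.9321139488613	0.589940056775245	7.13551896244229	11.5888982532205	1.06583836557559	5.49630872044891
mag_030	5.24945744331111	1.98596551981523	36.1226526941228	3.37636368413622	228.866162132457	22.5630554033467	52.2243700690576	209.567869271047	1.36292629545476	8.94951879441003	92.0154888780606	32.8731332117675
mag_031	0	29.1359754977284	0.398581607472078	4.74267687472935	1.50586756227365	2.1105956374716	0.438405995237945	0.385797965391225	3.67411729350662	23.9031777771966	16.5519931239275	17.4057000444613
mag_032	0	0	2.5136561796855	0.742281557834812	0.419526365757281	0	0	0.313766377630151	20.1647875949562	3.07931294030036	4.78533923673034	3.07645794266936
mag_033	5.47513214689736	2.39133052736201	16.5267454587601	0.582797257998072	0	2.24180397589457	3.23750514808983	0	0	0.231175275226249	0	0
mag_034	25.3570621844592	7.28591726658893	0.499987473147591	0.906608647677774	2.43029414509349	4.65962130431631	3.21654080996609	0	8.76830059630618	2.09441619710919	2.8928431468036	0
mag_035	1.83628679526252	0.434058099165969	26.7439010518431	0.455329166680175	1.47472313243133	7.52810712992912	1.97486988161979	0.292355706159237	0	6.3315698695383	0.46537560443606	3.71650943813856
mag_036	0	10.6930150682293	6.93453070757772	5.05634175687162	1.22757817891777	1.89305892829292	0.985572494840008	11.9533098261151	0.53998441345847	0.816824039300085	14.9814961705447	1.7308048754168
mag_037	0.236614284849651	0	0	0.241514718420124	0	0	0.49130498916953	0.451056418729926	0.685822883821554	0.500778386732661	2.33453591614905	1.59629822009517
mag_038	0	0	0	0.395488597429516	6.85250689477166	0.406466665812931	0	0	0.431344229754811	0.433448091744122	0.380734568141176	2.77538037075087
mag_039	0	4.07556962187893	15.3450381697979	0.697852882402297	0.576176889109773	2.23122462352895	2.00527849720459	57.6586364227251	0.223843962630842	0	5.35617031942022	0.282560364667895
mag_040	25.3780771803264	1.44205401521271	3.73507850566971	6.02771183360057	2.42628822610207	0.542683688042538	9.63331464285074	4.72343330798708	1.01100547555898	0.875246098278216	0	0
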