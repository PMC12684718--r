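mag_id	K00001	K00002	K00003	K00004	K00005	K00006	K00007	K00008	K00009	K00010	K00011	K00012	K00013	K00014	K00015	K00016	K00017	K00018	K00019	K00020	K00021	K00022	K00023	K00024	K00025
mag_001	0	0	2	0	0	1	0	0	2	0	1	1	1	0	0	0	1	1	3	2	0	1	1	0	0
mag_002	0	0	1	0	1	1	1	0	2	1	0	0	1	2	1	0	1	2	1	2	0	1	1	0	1
mag_003	0	0	3	0	0	1	1	1	1	1	3	1	0	0	1	2	1	2	0	1	1	0	0	2	0
mag_004	2	3	5	0	1	2	1	1	0	0	0	1	0	0	0	0	0	1	1	1	0	1	2	1	3
mag_005	3	0	0	2	1	2	4	1	0	2	1	0	0	0	1	0	0	1	0	0	0	2	0	1	1
mag_006	1	0	1	0	1	2	3	0	3	0	2	0	1	1	1	0	0	1	0	0	0	1	0	1	1
mag_007	0	1	0	1	2	1	1	0	2	0	2	0	0	0	0	0	3	0	2	2	1	0	1	0	0
mag_008	3	1	0	0	1	3	2	0	2	1	2	0	0	1	2	1	1	1	1	0	1	2	0	0	0
mag_009	2	1	1	1	3	1	0	1	0	0	2	0	2	2	0	1	1	3	1	0	0	1	1	1	0
mag_010	3	2	1	0	2	1	2	0	0	0	0	2	0	1	2	0	1	0	1	0	0	1	0	1	0
mag_011	3	1	3	1	0	3	0	1	0	0	0	1	0	0	1	2	0	1	2	0	0	2	0	2	0
mag_012	2	1	1	0	1	2	3	1	0	0	4	0	1	2	0	0	1	1	0	0	0	2	0	2	0
mag_013	1	0	2	1	1	1	2	0	2	0	0	3	0	0	0	0	2	2	1	0	1	0	0	1	1
mag_014	2	1	2	0	3	0	0	1	0	0	0	2	1	1	2	0	1	2	2	1	0	1	2	0	0
mag_015	1	1	2	0	1	0	0	0	1	2	0	2	0	1	1	2	1	0	1	0	2	2	0	1	0
mag_016	1	0	1	1	2	1	0	1	0	3	0	1	0	0	0	1	1	1	2	0	0	2	1	0	0
mag_017	1	0	2	0	0	1	2	2	2	0	1	0	0	0	0	0	1	1	0	0	1	2	1	0	1
mag_018	0	0	4	0	2	2	1	0	0	0	0	0	1	1	0	1	2	0	0	2	0	0	0	2	0
mag_019	1	2	2	0	2	0	1	1	1	2	1	0	1	0	0	0	1	1	1	3	1	3	0	0	1
mag_020	0	3	2	0	1	0	0	1	1	2	1	2	0	4	0	0	0	1	3	0	1	3	1	0	3
mag_021	2	1	1	2	1	1	1	1	0	2	0	2	0	1	1	0	0	1	1	1	1	0	1	1	3
mag_022	0	2	3	0	0	0	0	0	1	0	0	0	0	0	2	0	0	2	0	2	0	1	1	2	2
mag_023	1	3	4	0	2	2	2	0	0	1	1	1	0	0	1	1	1	1	0	0	1	2	0	1	0
mag_024	0	2	2	0	0	0	1	0	1	0	0	0	0	0	0	0	1	0	3	0	0	1	0	2	0
mag_025	0	0	1	0	0	2	3	0	0	1	0	0	0	1	2	1	1	0	0	2	0	0	0	3	1
mag_026	0	0	1	2	1	1	3	0	2	0	0	0	1	0	1	0	3	1	1	1	0	0	0	0	0
mag_027	1	1	0	1	1	0	0	0	1	1	0	0	1	0	0	0	2	0	0	2	0	3	2	1	0
mag_028	4	2	1	0	1	2	1	0	0	0	2	1	1	0	1	1	0	1	0	1	0	1	1	0	2
mag_029	2	1	3	0	0	0	1	0	1	0	2	0	1	2	2	1	0	2	0	1	0	1	0	1	1
mag_030	1	0	1	1	2	1	2	0	0	0	0	0	2	2	1	0	0	1	2	2	0	2	1	1	0
mag_031	1	1	2	0	2	2	2	0	0	2	1	1	1	0	0	0	1	2	0	0	0	3	0	2	0
mag_032	2	0	0	1	0	3	2	2	1	2	1	2	0	0	0	1	1	0	2	0	1	0	0	0	0
mag_033	3	1	1	1	0	0	1	0	0	0	0	1	1	2	0	0	0	0	1	0	0	0	0	1	1
mag_034	1	4	2	1	2	1	2	0	2	1	2	0	2	0	0	0	1	0	2	0	1	3	0	1	0
mag_035	0	0	0	1	2	3	2	1	0	0	1	0	0	1	0	1	1	1	0	1	0	1	0	0	2
mag_036	0	1	1	0	1	1	0	0	0	3	0	1	0	1	0	0	1	0	0	0	1	0	1	1	0
mag_037	0	3	0	1	0	1	3	0	0	0	1	0	0	2	2	0	1	1	2	0	0	2	0	1	0
mag_038	2	0	0	0	0	0	2	1	0	0	1	0	1	0	0	0	1	1	0	0	1	1	0	1	2
mag_039	1	1	2	0	1	1	3	1	0	0	0	1	0	0	0	0	2	1	1	1	0	0	1	0	0
mag_040	2	1	1	0	0	1	0	2	1	1	2	0	0	1	0	1	1	0	2	1	0	1	0	0	2
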