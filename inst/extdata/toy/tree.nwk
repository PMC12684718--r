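(((((mag_001:0.3506216327,((((mag_002:0.05756100879,mag_003:0.05756100879):0.0268410178,mag_004:0.08440202658):0.05758279108,(mag_005:0.02180455442,mag_006:0.02180455442):0.1201802632):0.1789779752,mag_007:0.3209627929):0.02965883979):0.08137435781,((mag_008:0.06871974834,mag_009:0.06871974834):0.1162276448,mag_010:0.1849473932):0.2470485973):0.1003691743,mag_011:0.5323651648):0.4176348352,(((mag_012:0.1318797838,(mag_013:0.02403377817,mag_014:0.02403377817):0.1078460057):0.4293988266,(((mag_015:0.06249292379,(mag_016:0.02137577687,mag_017:0.02137577687):0.04111714692):0.01179344499,mag_018:0.07428636878):0.2052337382,mag_019:0.2795201069):0.2817585035):0.1954587985,mag_020:0.756737409):0.193262591):0.05,((((mag_021:0.0125680302,mag_022:0.0125680302):0.4132813799,(mag_023:0.05832417575,mag_024:0.05832417575):0.3675252343):0.1241505899,(((mag_025:0.08900594465,mag_026:0.08900594465):0.2227296476,mag_027:0.3117355922):0.116748169,(mag_028:0.3732149571,(mag_029:0.110544282,mag_030:0.110544282):0.2626706751):0.05526880416):0.1215162388):0.09,(((mag_031:0.1406148637,mag_032:0.1406148637):0.1685447662,(mag_033:0.2558774904,(mag_034:0.1020464651,(mag_035:0.06848340621,(mag_036:0.06683346888,mag_037:0.06683346888):0.001649937323):0.03356305889):0.1538310253):0.05328213952):0.2408403701,((mag_038:0.1528707727,mag_039:0.1528707727):0.3154673622,mag_040:0.4683381349):0.08166186511):0.09):0.36);
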