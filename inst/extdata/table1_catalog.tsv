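accession	family	clade	organism	motifs	homologs
ABL86758	BPP	ABL	Bacillus subtilis ARRMK33	YG:159-160;EGMAAD:211-216;DIEG:258-261;DG:314-315	AAC31775.1;AAC38573.1;AAM74021.1;ABP02074.1;ACZ57955.1;AEC13691.1;AFD29183.1;AVV65759.1;CAM58513.1;CRL66425.1;O31097;O66037;P42094;ABQ66899.1;CQR59166.1;MBO9525759.1
AQX17444	BPP	AQX	Pseudomonas sp. FB15	YG:418-419;EGCVAD:468-473;DVEG:514-517;DG:571-572	AAN55555.1;ADZ99372.1;ADZ99940.1;AEQ29499.1;AHM26864.1;AJF36073.1;UNF21334.1
ACJ35482	BPP	ACJ	Pedobacter nyackensis MJ11	MG:170-171;ESIAVD:229-234;DNEG:274-277;DG:329-330
QJA16365	BPP	QJA	Arthrobotrys oligospora ATCC 24927	YG:529-530;EGCVVD:583-588;DVEG:632-635;DG:691-692
AAA32705	HAP	AAA	Aspergillus niger	RHGARYP:81-87;HD:361-362	AAB96872.1;AAN10115.1;AAU93517.1;CAC48195.1;D4ANW6;O00085;O00093;O00100;O00107;P34753;Q0CLV1;Q9C1T1
ABG88857	HAP	ABG	Aspergillus niger strain WP1	RHGERYP:65-71;HD:321-322	2GFI_A;AAA02934.1;ABU49229.1;ADF49635.1;P34755;ABN04184.1
WP_057099050	HAP	050	Bacteroides thetaiotaomicron	RHGARFP:58-64;HAE:323-325
ACJ51391	HAP	ACJ	Bifidobacterium longum	RHGSRGL:74-80;HAE:429-431
WP_027265797	HAP	797	Legionella pneumophila	RHGDRTP:33-39;HD:280-281
WP_198495896	HAP	896	Metagenome samples	RHGNRTP:45-51;HD:293-294	JGI1357J11328_100303543
AAM23271	HAP	AAM	Klebsiella sp. strain ASR1	RHGIRPP:40-46;HD:306-307	AAL59319.1;ABW76125.1
AAR89622	HAP	AAR	Citrobacter freundii	RHGVRAP:38-44;HD:324-325	AAR87658.1;AAS45884.1;ABI95370.1;ABI98040.1;ABX75421.1;ABX80238.1;ACB54699.1;AFG25721.1;BAQ94585.1;QPN96261.1;P07102;WP_117343249.1;P19926;AIE90144.1
AAQ13669	CP	AAQ	Selenomonas ruminantium JY35	DH:223-224;HCEAGVGRT:251-259	ABA18187.1;ABC69358.4;ABC69359.4;ABC69361.2;ABC69367.2;ADG23212.1;ADG23213.1;CAE79111.1;WP_011590872.1
AWN00236	CP	AWN	Streptacidiphilus melanogenes	YF:240-241;HCTAGKDRT:268-276
ACR23329	PAP	ACR	Triticum aestivum	GDLG:193-196;GNHE:277-280;VAGWH:356-360;GHVH:396-399	ANG56539.1;ACR23326.1;ACR23333.1;ACR23335.1;AEG77017.1;ACR23327.1;ACR23331.1;AEG77016.1;ADG07931.1;AEA39182.1;ACR23328.1;ACR23332.1;ABP96799.1;AAX71115.1;AAN74650.1;ACD87745.1;ADM32493.1;ADM88044.1;ADI50286.1;AAK49438.1;AAE83899.1;AAX20028.1;AJK28063.1;WP_017329228.1
XP_004504591	PAP	XP	Cicer arietinum	GDWG:52-55;GNHD:123-126;VVGHH:215-219;GHDH:252-255	NP_001242830.2
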