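name	regulator	targets
hsa_miR_326_M	hsa-miR-326	ARHGDIA;CEP250;MYO6;TYR;PWP2;RCBTB2;POLR3F
hsa_miR_323_3p_M	hsa-miR-323-3p	BCLAF1;SUMO1;TMBIM6;FAM168B
hsa_miR_16_M	hsa-miR-16	NFATC3;ETNK1;BMX;NCOR2;POLR3F
hsa_let_7e_M	hsa-let-7e	CLP1;NGF
FOXO3_M	FOXO3	MICAL1;SAMD8;FUBP3;ATXN10;ADAM11;RAB5C;MRPS24;DPAGT1;GPS1;SNRPC;SUMO1;TWF1;SAR1A;PICALM;TXNDC5;HEXIM2;TRIP12;ZDHHC15;SEMA4G;EFHD2
hsa_miR_22_M	hsa-miR-22	SLC6A1;SLC35A4
hsa_miR_326_NM	hsa-miR-326	MTERFD2;ARHGDIA;PCSK4;CEP250;PTRF;MYO6;ST6GALNAC6
hsa_miR_204_M	hsa-miR-204	CHD5;ATF2;POU2F2;TOMM70A;WDR26;SPOP;FAM168B;PLAA;WASF2;SRXN1
POU2F2_M	POU2F2	SPIB;C20ORF43;SUCNR1;PTRF
NFYB_M	NFYB	NTN4;CACNG5;C12ORF10;TUBA1B;CALB2;RGMA;APOC3;PGD;NDUFV1;CHDH;FBXO24;TCTN2
hsa_miR_30a_M	hsa-miR-30a	CREB1;PAWR;NEDD4;RRAS2;VPS26B;TBC1D2B;HTR4;ACAP2;ZFAND5;SPAG9;MICAL1;ATG5
hsa_miR_7_M	hsa-miR-7	PDCD2;POLR2E;NF2;FAM168B;MEGF9
CUX1_NM	CUX1	RUNX1;IFITM2;MARCH5;GPR21;RPL35;TNFRSF10B;CFP;SDHAF2;NUP62CL;YARS;NAGK;GRAMD1A;PLXNB2;BCL2L13;METTL11A;MARK3;ITM2A;HIP1R;BSG
FOXO3_NM	FOXO3	MAFF;LEPROT;MICAL1;PSME1;SAMD8;FUBP3;ATXN10
STAT1_NM	STAT1	MYBL1;MAFF;POLA1;EXOG;PGM1;ZDHHC4;WDR24;AMFR;RAD52;TMEM208;MRPL34;GCHFR;ANKRD30A;TRO;LDHAL6A;SERPING1;RNASE4;ARPC5L;SRSF3;CD248
TP53_NM	TP53	ANKRD52;SLC25A20;PGM1;C1QTNF4;PKDCC
STAT1_M	STAT1	WDR24;RAD52;GCHFR
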