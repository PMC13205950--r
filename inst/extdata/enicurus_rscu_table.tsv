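species	amino_acid	codon	rscu	rscu_high	rscu_low	delta_rscu
E_scouleri	Ala	GCU	0.7568	0.3478	1.0612	-0.7134
E_scouleri	Ala	GCC	1.9459	2.6087	1.7959	0.8128
E_scouleri	Ala	GCA	1.1892	1.0435	1.1429	-0.0994
E_scouleri	Ala	GCG	0.1081	0	0	0
E_scouleri	Cys	UGU	0.6429	2	0	2
E_scouleri	Cys	UGC	1.3571	0	2	-2
E_scouleri	Asp	GAU	0.549	0.5	0.4615	0.0385
E_scouleri	Asp	GAC	1.451	1.5	1.5385	-0.0385
E_scouleri	Glu	GAA	1.7662	1.8	1.6667	0.1333
E_scouleri	Glu	GAG	0.2338	0.2	0.3333	-0.1333
E_scouleri	Phe	UUC	1.6988	1.4444	1.6364	-0.192
E_scouleri	Phe	UUU	0.3012	0.5556	0.3636	0.192
E_scouleri	Gly	GGU	0.4734	0.6154	0.2	0.4154
E_scouleri	Gly	GGC	0.9467	0.9231	0.6	0.3231
E_scouleri	Gly	GGA	1.8225	2.4615	2.6	-0.1385
E_scouleri	Gly	GGG	0.7574	0	0.6	-0.6
E_scouleri	His	CAU	0.2078	0	0.2353	-0.2353
E_scouleri	His	CAC	1.7922	2	1.7647	0.2353
E_scouleri	Ile	AUU	0.449	0.32	0.4651	-0.1451
E_scouleri	Ile	AUC	1.551	1.68	1.5349	0.1451
E_scouleri	Lys	AAA	1.9459	2	1.8889	0.1111
E_scouleri	Lys	AAG	0.0541	0	0.1111	-0.1111
E_scouleri	Leu	UUA	0.4218	0.2069	0.875	-0.6681
E_scouleri	Leu	UUG	0.1371	0	0	0
E_scouleri	Leu	CUU	0.5589	0.3448	0.75	-0.4052
E_scouleri	Leu	CUC	1.2337	1.1724	1.25	-0.0776
E_scouleri	Leu	CUA	3.3849	4	2.9375	1.0625
E_scouleri	Leu	CUG	0.2636	0.2759	0.1875	0.0884
E_scouleri	Met	AUA	1.5349	0.9333	1.5172	-0.5839
E_scouleri	Met	AUG	0.4651	1.0667	0.4828	0.5839
E_scouleri	Asn	AAU	0.1622	0	0.1053	-0.1053
E_scouleri	Asn	AAC	1.8378	2	1.8947	0.1053
E_scouleri	Pro	CCU	0.5111	0	1.125	-1.125
E_scouleri	Pro	CCG	0	0	0	0
E_scouleri	Pro	CCA	2	2.2609	1.75	0.5109
E_scouleri	Pro	CCC	1.4889	1.7391	1.125	0.6141
E_scouleri	Gln	CAA	1.8372	2	1.8947	0.1053
E_scouleri	Gln	CAG	0.1628	0	0.1053	-0.1053
E_scouleri	Arg	CGU	0.4	0	0.4444	-0.4444
E_scouleri	Arg	CGC	0.9333	1.1429	1.3333	-0.1904
E_scouleri	Arg	CGA	2.3333	2.8571	1.7778	1.0793
E_scouleri	Arg	CGG	0.3333	0	0.4444	-0.4444
E_scouleri	Ser	UCU	0.5902	0.2308	0.5	-0.2692
E_scouleri	Ser	UCC	1.9918	2.3077	2.125	0.1827
E_scouleri	Ser	UCA	2.041	1.8462	2.25	-0.4038
E_scouleri	Ser	UCG	0.123	0.2308	0	0.2308
E_scouleri	Ser	AGU	0.2213	0	0.375	-0.375
E_scouleri	Ser	AGC	1.0328	1.3846	0.75	0.6346
E_scouleri	Thr	ACU	0.6667	0.4706	1.0667	-0.5961
E_scouleri	Thr	ACC	1.8222	1.8824	1.8	0.0824
E_scouleri	Thr	ACA	1.4667	1.6471	1.0667	0.5804
E_scouleri	Thr	ACG	0.0444	0	0.0667	-0.0667
E_scouleri	Val	GUU	0.5676	0	0.2963	-0.2963
E_scouleri	Val	GUC	1.5135	1.6667	2.0741	-0.4074
E_scouleri	Val	GUA	1.4865	2.3333	1.4815	0.8518
E_scouleri	Val	GUG	0.4324	0	0.1481	-0.1481
E_scouleri	Trp	UGA	1.8333	1.7778	1.7333	0.0445
E_scouleri	Trp	UGG	0.1667	0.2222	0.2667	-0.0445
E_scouleri	Tyr	UAU	0.5055	0.8	0.5714	0.2286
E_scouleri	Tyr	UAC	1.4945	1.2	1.4286	-0.2286
E_schistaceus	Ala	GCU	0.6897	0.7	0.8485	-0.1485
E_schistaceus	Ala	GCC	1.8544	1.8	2.303	-0.503
E_schistaceus	Ala	GCA	1.3333	1.5	0.8485	0.6515
E_schistaceus	Ala	GCG	0.1226	0	0	0
E_schistaceus	Cys	UGU	0.3571	0	0	0
E_schistaceus	Cys	UGC	1.6429	2	2	0
E_schistaceus	Asp	GAU	0.72	0	0.7692	-0.7692
E_schistaceus	Asp	GAC	1.28	2	1.2308	0.7692
E_schistaceus	Glu	GAA	1.7436	1.6364	1.8824	-0.246
E_schistaceus	Glu	GAG	0.2564	0.3636	0.1176	0.246
E_schistaceus	Phe	UUC	0.3855	0.5217	0.5882	-0.0665
E_schistaceus	Phe	UUU	1.6145	1.4783	1.4118	0.0665
E_schistaceus	Gly	GGU	0.5087	0	0.9412	-0.9412
E_schistaceus	Gly	GGC	0.9711	0.2353	0.9412	-0.7059
E_schistaceus	Gly	GGA	1.9422	3.2941	2.1176	1.1765
E_schistaceus	Gly	GGG	0.578	0.4706	0	0.4706
E_schistaceus	His	CAU	0.4533	0.6667	0.5455	0.1212
E_schistaceus	His	CAC	1.5467	1.3333	1.4545	-0.1212
E_schistaceus	Ile	AUU	0.607	0.3902	0.8	-0.4098
E_schistaceus	Ile	AUC	1.393	1.6098	1.2	0.4098
E_schistaceus	Lys	AAA	1.8919	1.8571	2	-0.1429
E_schistaceus	Lys	AAG	0.1081	0.1429	0	0.1429
E_schistaceus	Leu	UUA	0.704	0.7333	0.5684	0.1649
E_schistaceus	Leu	UUG	0.1051	0.0667	0	0.0667
E_schistaceus	Leu	CUU	0.5779	0.5333	0.7579	-0.2246
E_schistaceus	Leu	CUC	1.0508	1.2667	0.8211	0.4456
E_schistaceus	Leu	CUA	3.268	3.1333	3.7895	-0.6562
E_schistaceus	Leu	CUG	0.2942	0.2667	0.0632	0.2035
E_schistaceus	Met	AUA	1.5285	1.7143	1.0588	0.6555
E_schistaceus	Met	AUG	0.4715	0.2857	0.9412	-0.6555
E_schistaceus	Asn	AAU	0.5766	0.8571	0.5333	0.3238
E_schistaceus	Asn	AAC	1.4234	1.1429	1.4667	-0.3238
E_schistaceus	Pro	CCU	0.7458	0.6154	0.5926	0.0228
E_schistaceus	Pro	CCG	1.0621	0.9231	1.037	-0.1139
E_schistaceus	Pro	CCA	2.1243	2	2.3704	-0.3704
E_schistaceus	Pro	CCC	0.0678	0.4615	0	0.4615
E_schistaceus	Gln	CAA	1.8353	1.875	1.8667	0.0083
E_schistaceus	Gln	CAG	0.1647	0.125	0.1333	-0.0083
E_schistaceus	Arg	CGU	0.4	0	0.3636	-0.3636
E_schistaceus	Arg	CGC	0.8	0	1.4545	-1.4545
E_schistaceus	Arg	CGA	2.4667	4	1.8182	2.1818
E_schistaceus	Arg	CGG	0.3333	0	0.3636	-0.3636
E_schistaceus	Ser	UCU	0.7531	0.6486	0.4865	0.1621
E_schistaceus	Ser	UCC	1.7322	1.9459	1.6216	0.3243
E_schistaceus	Ser	UCA	2.159	2.2703	2.2703	0
E_schistaceus	Ser	UCG	0.1004	0	0	0
E_schistaceus	Ser	AGU	0.251	0.1622	0.3243	-0.1621
E_schistaceus	Ser	AGC	1.0042	0.973	1.2973	-0.3243
E_schistaceus	Thr	ACU	0.8182	1.3103	0.5556	0.7547
E_schistaceus	Thr	ACC	1.7576	1.5172	1.5556	-0.0384
E_schistaceus	Thr	ACA	1.3788	1.1034	1.7778	-0.6744
E_schistaceus	Thr	ACG	0.0455	0.069	0.1111	-0.0421
E_schistaceus	Val	GUU	0.8219	0.4444	0.4615	-0.0171
E_schistaceus	Val	GUC	1.0959	1.3333	1.2308	0.1025
E_schistaceus	Val	GUA	1.6712	2.2222	2	0.2222
E_schistaceus	Val	GUG	0.411	0	0.3077	-0.3077
E_schistaceus	Trp	UGA	1.9524	2	2	0
E_schistaceus	Trp	UGG	0.0476	0	0	0
E_schistaceus	Tyr	UAU	0.383	0	0.5455	-0.5455
E_schistaceus	Tyr	UAC	1.617	2	1.4545	0.5455
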