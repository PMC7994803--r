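# Published transfer-window table (Ma), transcribed verbatim from the
# dating study's results: per scenario and analysis, the older bound (max),
# younger bound (min) and width of each transfer window. Printed widths
# occasionally differ by 1 Ma from older-younger because the published
# bounds are rounded from unrounded HPD limits.
scenario	event	analysis	older	younger	width
stiller	Rho->Cry	mcmctree_ac	1658	1281	377
stiller	Rho->Cry	mcmctree_uc	1453	1158	296
stiller	Rho->Cry	phylobayes_ac	1636	1335	301
stiller	Rho->Cry	phylobayes_uc	1517	1057	461
stiller	Rho->Cry	beast_uc	1502	1210	292
stiller	Cry->Och	mcmctree_ac	1298	623	675
stiller	Cry->Och	mcmctree_uc	1446	804	642
stiller	Cry->Och	phylobayes_ac	1518	918	600
stiller	Cry->Och	phylobayes_uc	1517	747	771
stiller	Cry->Och	beast_uc	1441	786	654
stiller	Och->Hap	mcmctree_ac	1298	623	675
stiller	Och->Hap	mcmctree_uc	1446	804	642
stiller	Och->Hap	phylobayes_ac	1518	1051	467
stiller	Och->Hap	phylobayes_uc	1517	747	771
stiller	Och->Hap	beast_uc	1441	786	654
stiller	Och->Myz	mcmctree_ac	1298	696	602
stiller	Och->Myz	mcmctree_uc	1446	1017	428
stiller	Och->Myz	phylobayes_ac	1518	1138	380
stiller	Och->Myz	phylobayes_uc	1517	1075	443
stiller	Och->Myz	beast_uc	1441	1022	419
bodyl	Rho->Cry	mcmctree_ac	1658	1281	377
bodyl	Rho->Cry	mcmctree_uc	1453	1158	296
bodyl	Rho->Cry	phylobayes_ac	1636	1335	301
bodyl	Rho->Cry	phylobayes_uc	1517	1057	461
bodyl	Rho->Cry	beast_uc	1502	1210	292
bodyl	Cry->Och	mcmctree_ac	1298	623	675
bodyl	Cry->Och	mcmctree_uc	1446	804	642
bodyl	Cry->Och	phylobayes_ac	1518	918	600
bodyl	Cry->Och	phylobayes_uc	1517	747	771
bodyl	Cry->Och	beast_uc	1441	786	654
bodyl	Cry->Hap	mcmctree_ac	1658	579	1079
bodyl	Cry->Hap	mcmctree_uc	1453	707	747
bodyl	Cry->Hap	phylobayes_ac	1636	1051	585
bodyl	Cry->Hap	phylobayes_uc	1517	573	944
bodyl	Cry->Hap	beast_uc	1502	624	878
bodyl	Hap->Myz	mcmctree_ac	1520	696	824
bodyl	Hap->Myz	mcmctree_uc	1453	1017	436
bodyl	Hap->Myz	phylobayes_ac	1636	1138	498
bodyl	Hap->Myz	phylobayes_uc	1517	1075	443
bodyl	Hap->Myz	beast_uc	1502	1022	480
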