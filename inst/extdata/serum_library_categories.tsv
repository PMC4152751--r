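category	C1	C2	C3	H1	H2	H3
total_reads	13191837	17201872	11517031	14530924	9044505	12042843
clean_reads	12655313	14664409	10730467	14039577	8516261	11321127
unique_srnas	40566	82548	106967	39455	26117	26126
exon_antisense	1154	863	128	609	1429	1532
exon_sense	1811	2838	259	1607	2704	4668
intron_antisense	4478	5037	689	1997	5991	8048
intron_sense	5519	5163	939	2738	8544	11680
miRNA	3510595	6458542	731	7478939	4204224	5994620
rRNA	55449	255219	15013	136111	53970	102897
repeat	20345	19040	3736	8511	24645	35847
scRNA	1940	4393	334	1680	6295	7935
snRNA	2589	3819	422	4951	8739	13710
snoRNA	202	478	114	358	180	303
tRNA	11172	27983	3469	21598	15768	19515
unannotated	9040059	7881033	81129	6380477	4183759	5120372
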