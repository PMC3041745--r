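# Annotated feature table of the Calanus sinicus mitochondrial contig
# (near-complete assembly; trnR and trnC missing, head/tail of the long
# non-coding region LNR1 unsequenced, hence linear topology).
# Coordinates are 1-based inclusive on the reference (H) strand.
# 'length' and 'intergenic' are the published declared values; 'intergenic'
# is the spacer between a feature and its upstream neighbour (NA = the open
# wrap-around spacer of the linear contig).
# topology: linear
# total_length: 20460
name	kind	strand	start	end	start_codon	stop_codon	length	intergenic
rrnL	rRNA	H	2244	3382	.	.	1139	NA
trnV	tRNA	H	3383	3447	.	.	65	3
trnD	tRNA	H	3457	3518	.	.	62	9
trnT	tRNA	H	3531	3593	.	.	63	12
trnS2	tRNA	L	3594	3650	.	.	57	0
cox1	PCG	L	3660	5207	ATA	TAA	1548	9
nad4L	PCG	H	5336	5671	ATA	TAG	336	128
cytb	PCG	L	5751	6887	ATG	TAA	1137	79
nad6	PCG	L	6898	7377	ATT	TAG	480	10
rrnS	rRNA	L	7429	8082	.	.	654	51
trnG	tRNA	L	8083	8146	.	.	64	3
nad1	PCG	L	8147	9063	ATA	TA	917	0
trnF	tRNA	L	9064	9126	.	.	63	0
trnI	tRNA	L	9131	9193	.	.	63	4
nad5	PCG	H	9231	10954	ATT	TA	1724	37
trnH	tRNA	H	10955	11017	.	.	63	0
trnA	tRNA	H	12788	12851	.	.	64	1770
trnY	tRNA	H	12852	12912	.	.	61	0
trnE	tRNA	L	12908	12971	.	.	64	-5
trnQ	tRNA	L	13002	13067	.	.	66	30
trnL1	tRNA	L	13080	13143	.	.	64	12
trnP	tRNA	L	13178	13240	.	.	63	34
trnM	tRNA	L	13246	13309	.	.	64	5
trnK	tRNA	L	13312	13374	.	.	63	2
trnW	tRNA	L	13376	13439	.	.	64	1
trnS1	tRNA	L	13439	13498	.	.	60	-1
trnN	tRNA	L	13498	13565	.	.	68	-1
cox2	PCG	L	13571	14275	ATT	TAA	705	5
nad3	PCG	H	14338	14691	ATT	TAA	354	62
cox3	PCG	L	14794	15585	ATG	TAA	792	102
nad4	PCG	H	16357	17658	ATA	TAA	1302	771
trnL2	tRNA	H	17663	17728	.	.	66	4
nad2	PCG	H	17729	18697	ATA	TAA	969	0
atp8	PCG	H	18870	19031	ATT	TAA	162	172
atp6	PCG	H	19034	19744	ATG	TAG	711	2
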