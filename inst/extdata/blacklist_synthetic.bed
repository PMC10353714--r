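chr1	121700000	125100000	chr1_cen	centromere
chr1	143184587	143404587	gap_1q	gap
chr10	38000000	41600000	chr10_cen	centromere
chr11	51000000	55800000	chr11_cen	centromere
chr12	34700000	37200000	chr12_cen	centromere
chr13	0	2000000	gap_13p	gap
chr13	16000000	18900000	chr13_cen	centromere
chr14	0	2000000	gap_14p	gap
chr14	16000000	18200000	chr14_cen	centromere
chr14	21540000	22560000	TRA	IG_TR
chr14	105550000	106880000	IGH	IG_TR
chr15	0	2000000	gap_15p	gap
chr15	17000000	20700000	chr15_cen	centromere
chr16	36300000	38300000	chr16_cen	centromere
chr17	22700000	27400000	chr17_cen	centromere
chr18	15400000	20900000	chr18_cen	centromere
chr19	24400000	28100000	chr19_cen	centromere
chr2	88790000	90280000	IGK	IG_TR
chr2	91800000	96000000	chr2_cen	centromere
chr20	26400000	30000000	chr20_cen	centromere
chr21	0	2000000	gap_21p	gap
chr21	10900000	13000000	chr21_cen	centromere
chr22	0	2000000	gap_22p	gap
chr22	13700000	17400000	chr22_cen	centromere
chr22	21990000	22930000	IGL	IG_TR
chr3	87800000	94000000	chr3_cen	centromere
chr4	48200000	51800000	chr4_cen	centromere
chr5	46100000	50100000	chr5_cen	centromere
chr6	58500000	62600000	chr6_cen	centromere
chr7	38240000	38370000	TRG	IG_TR
chr7	58100000	62400000	chr7_cen	centromere
chr7	141990000	142510000	TRB	IG_TR
chr8	43200000	47200000	chr8_cen	centromere
chr9	42200000	45500000	chr9_cen	centromere
chrX	58100000	63800000	chrX_cen	centromere
chrX	114300000	114430000	gap_Xq	gap
chrY	10300000	10600000	chrY_cen	centromere
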