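assembly_id	locus	chromosome	seq_id	start	end	strand	reported_length_bp	ig_gene_number
Kamilah_GGO_v0	IGH	14	CM017861.1	86452632	87593842	REV	1141211	164
Susie3	IGH	14	LT578329.1	86149321	87571187	REV	1421867	185
NHGRI_mGorGor1-v1.1-0.2.freeze_mat	IGH	14	CM054596.1	114386608	115697767	REV	1311160	174
NHGRI_mGorGor1-v1.1-0.2.freeze_pat	IGH	14	CM054572.1	118187703	119503099	REV	1315397	177
Kamilah_GGO_v0	IGK	2A	CM017848.1	104237816	105130673	REV	892858	49
Susie3	IGK	2A	LT578338.1	17629982	18328204	FWD	698223	47
NHGRI_mGorGor1-v1.1-0.2.freeze_mat	IGK	2A	CM054583.1	94854218	96227846	REV	1373629	50
NHGRI_mGorGor1-v1.1-0.2.freeze_pat	IGK	2A	CM054559.1	94027569	94921140	REV	893572	49
Kamilah_GGO_v0	IGL	22	CM017869.1	4187005	5025689	FWD	838685	90
Susie3	IGL	22	LT578337.1	5400563	6277394	FWD	876832	100
NHGRI_mGorGor1-v1.1-0.2.freeze_mat	IGL	22	CM054604.1	16012935	16839685	FWD	826751	93
NHGRI_mGorGor1-v1.1-0.2.freeze_pat	IGL	22	CM054580.1	14038805	14911038	FWD	872234	102
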