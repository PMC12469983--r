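cell_id	locus	v_call	j_call	c_call	junction	junction_aa	duplicate_count	productive
AAACCTGAGAAACGAG-1	TRA	TRAV10*01	TRAJ12*01	TRAC	TGTGTGGTGAGCGATAACACCGGCGGCTTCAAAACCATCTTT	CVVSDNTGGFKTIF	4	TRUE
AAACCTGAGAAACGAG-1	TRB	TRBV28*01	TRBJ1-2*01	TRBC1	TGTGCCAGCAGCCTGAGCTACGGCTACACCTTT	CASSLSYGYTF	7	TRUE
AAACCTGTCAGGCGAA-1	TRA	TRAV12-2*01	TRAJ23*01	TRAC	TGTGCCGTGAACTACAACCAGGGCGGCAAGCTGATCTTT	CAVNYNQGGKLIF	3	TRUE
AAACCTGTCAGGCGAA-1	TRA	TRAV2*01	TRAJ33*01	TRAC	TGTGCCGTGGACAGCAACTACCAGCTGATCTGGTTT	CAVDSNYQLIWF	1	TRUE
AAACCTGTCAGGCGAA-1	TRB	TRBV14*01	TRBJ2-1*01	TRBC2	TGTGCCAGCAGCCAGGACCGGGGCAACGAGCAGTTT	CASSQDRGNEQF	6	TRUE
AAACGGGCAGTTCGTA-1	TRB	TRBV7-2*01	TRBJ2-3*01	TRBC2	TGTGCCAGCAGCTTCACCGACACCCAGTACTTT	CASSFTDTQYF	5	TRUE
AAAGATGAGCGATTCT-1	TRA	TRAV26-1*01	TRAJ45*01	TRAC	TGTATCGTGCGGGGCGGCGGCGCCGACGGCCTGACCTTT	CIVRGGGADGLTF	2	TRUE
AAAGATGAGCGATTCT-1	TRB	TRBV19*01	TRBJ1-5*01	TRBC1	TGTGCCAGCAGCATCGGCCAGCCCCAGCACTTT	CASSIGQPQHF	3	TRUE
AAAGATGAGCGATTCT-1	TRB	TRBV6-2*01	TRBJ1-1*01	TRBC1	TGTGCCAGCAGCGAGGCCTTT	CASSEAF	1	FALSE
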