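barcode,is_cell,contig_id,high_confidence,length,chain,v_gene,d_gene,j_gene,c_gene,full_length,productive,cdr3,cdr3_nt,reads,umis
AAACCTGAGAAACGAG-1,TRUE,AAACCTGAGAAACGAG-1_contig_1,TRUE,521,TRA,TRAV10*01,None,TRAJ12*01,TRAC,TRUE,TRUE,CVVSDNTGGFKTIF,TGTGTGGTGAGCGATAACACCGGCGGCTTCAAAACCATCTTT,1021,4
AAACCTGAGAAACGAG-1,TRUE,AAACCTGAGAAACGAG-1_contig_2,TRUE,498,TRB,TRBV28*01,TRBD1,TRBJ1-2*01,TRBC1,TRUE,TRUE,CASSLSYGYTF,TGTGCCAGCAGCCTGAGCTACGGCTACACCTTT,2410,7
AAACCTGTCAGGCGAA-1,TRUE,AAACCTGTCAGGCGAA-1_contig_1,TRUE,509,TRA,TRAV12-2*01,None,TRAJ23*01,TRAC,TRUE,TRUE,CAVNYNQGGKLIF,TGTGCCGTGAACTACAACCAGGGCGGCAAGCTGATCTTT,899,3
AAACCTGTCAGGCGAA-1,TRUE,AAACCTGTCAGGCGAA-1_contig_2,TRUE,477,TRB,TRBV14*01,TRBD2,TRBJ2-1*01,TRBC2,TRUE,TRUE,CASSQDRGNEQF,TGTGCCAGCAGCCAGGACCGGGGCAACGAGCAGTTT,1720,6
AAACGGGCAGTTCGTA-1,TRUE,AAACGGGCAGTTCGTA-1_contig_1,TRUE,466,TRB,TRBV7-2*01,TRBD1,TRBJ2-3*01,TRBC2,TRUE,TRUE,CASSFTDTQYF,TGTGCCAGCAGCTTCACCGACACCCAGTACTTT,1544,5
AAACGGGCAGTTCGTA-1,FALSE,AAACGGGCAGTTCGTA-1_contig_2,TRUE,402,TRA,TRAV2*01,None,TRAJ33*01,TRAC,TRUE,TRUE,CAVDSNYQLIWF,TGTGCCGTGGACAGCAACTACCAGCTGATCTGGTTT,310,1
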