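guide_id	gene	spacer	role
sgLmo2-1	Lmo2	CGGACTCTCATCAGGGCGGA	positive_control
sgLmo2-2	Lmo2	TCCTGAATTGGTCGCTGTTC	positive_control
sgLmo2-3	Lmo2	ACATCTACGTCGGGTGTAAC	positive_control
sgRosa26-1	Rosa26	ATCTTCATGGGCGCGTATAA	negative_control
sgRosa26-2	Rosa26	AATGGGTAGTGCGGTTCACC	negative_control
sgRosa26-3	Rosa26	ACGGCAGACGCGCGTGTCAA	negative_control
sgTfdp1-1	Tfdp1	TCCCACTACTTCGCACGTTC	candidate
sgTfdp1-2	Tfdp1	GCTCAGCATACCCGCCTTAC	candidate
sgTfdp1-3	Tfdp1	GTCCTGCAAAGAGCGTACCT	candidate
sgUhrf1-1	Uhrf1	ACCATGAAGAGTTTCCTTCC	positive_control
sgUhrf1-2	Uhrf1	TTCGGGATTCTTGAGCATGA	positive_control
sgUhrf1-3	Uhrf1	AAGAAGAGAAGATCGTGCGT	positive_control
sgZfp001-1	Zfp001	TAACTAGGGGTGACCACCCA	candidate
sgZfp001-2	Zfp001	TAAGCTCATCACGCCCCGCA	candidate
sgZfp001-3	Zfp001	ATTGGTCGTACGCTGAGCCC	candidate
sgZfp002-1	Zfp002	CCTTGTCTTGGGGTAACAGA	candidate
sgZfp002-2	Zfp002	TATCCGCGATGGAGACCCGG	candidate
sgZfp002-3	Zfp002	TTAAAAGCAGGACGGCCATT	candidate
sgZfp003-1	Zfp003	ATGCAGAGAGGCGACCCATC	candidate
sgZfp003-2	Zfp003	GTGGCGGGGCGTACTTTGAA	candidate
sgZfp003-3	Zfp003	CGGAGGCGGATGGTGCTTTA	candidate
sgZfp004-1	Zfp004	ATTAGCCGTTGAGTGCCCGC	candidate
sgZfp004-2	Zfp004	AGATATGCGGGGCTGGCCTT	candidate
sgZfp004-3	Zfp004	GGTATGCCATGTCGCTTACA	candidate
sgZfp005-1	Zfp005	TGAGGTGATACCGGTAAGCC	candidate
sgZfp005-2	Zfp005	CCCGAACGACTGATAGAATT	candidate
sgZfp005-3	Zfp005	ACGAAGTTGCCTACTGCCTT	candidate
sgZfp006-1	Zfp006	GTCCGGAGATGTGCACGGGA	candidate
sgZfp006-2	Zfp006	CGATGAATTCGCCTCGAGCA	candidate
sgZfp006-3	Zfp006	TAACGGGTAAGTTGCCGTGC	candidate
sgZfp007-1	Zfp007	GTTGCAGACTCTTTACCTTT	candidate
sgZfp007-2	Zfp007	TAGTGGTAAACATGTGGGGT	candidate
sgZfp007-3	Zfp007	TCCCCGGTTCATTGCCTAAA	candidate
sgZfp008-1	Zfp008	CCTAGTTAGTTAAGGCGAAA	candidate
sgZfp008-2	Zfp008	CAACCACGAGAATTTCGAAA	candidate
sgZfp008-3	Zfp008	ACCGAAGGCAGGAGCCTCTG	candidate
sgZfp009-1	Zfp009	GCAACGAGCTTCCTCGTGAG	candidate
sgZfp009-2	Zfp009	AGTGCTTGGTATTCATTGCC	candidate
sgZfp009-3	Zfp009	CGAACATGCAAGAGATCTGA	candidate
sgZfp010-1	Zfp010	CCCTCCCTAAACTTGACAAC	candidate
sgZfp010-2	Zfp010	CGGTTATGGGCCGTTACGGG	candidate
sgZfp010-3	Zfp010	ACTATGTCTGTGCCTCCTTG	candidate
sgZfp011-1	Zfp011	AGAGAACGCTGACATGAGCC	candidate
sgZfp011-2	Zfp011	GTGATTATGTGTGTTGTAAG	candidate
sgZfp011-3	Zfp011	GCTTGCTCAAATTACACAAC	candidate
sgZfp012-1	Zfp012	CTTAGAATGAGGTCGACGAC	candidate
sgZfp012-2	Zfp012	AGTACCCTATCCCTAGCTGC	candidate
sgZfp012-3	Zfp012	GGGGTCTTGGCTCCAACTTG	candidate
sgZfp013-1	Zfp013	CACGTCCGGGTAAATCTATA	candidate
sgZfp013-2	Zfp013	AAATCGTGTCGACTAAGCGA	candidate
sgZfp013-3	Zfp013	GTGCGGGACGTAAGACCCAC	candidate
sgZfp014-1	Zfp014	GCGATCCGTGAGTTGAGCGA	candidate
sgZfp014-2	Zfp014	TGAGCCCGCGGGGAGCGAGG	candidate
sgZfp014-3	Zfp014	GAATCGTGGCGTGGTTCCAA	candidate
sgZfp015-1	Zfp015	GTCAATGGCATACGGCCGTG	candidate
sgZfp015-2	Zfp015	TAACAGCATACCGGTGACAA	candidate
sgZfp015-3	Zfp015	TACTCTTCGAAAAGTCATGT	candidate
sgZfp016-1	Zfp016	CTATAGGTCAGCACTAATTA	candidate
sgZfp016-2	Zfp016	TGACCTTCCAGGGTCATGAT	candidate
sgZfp016-3	Zfp016	GTGAATTTCCTTCTACTAGC	candidate
sgZfp017-1	Zfp017	ACTAGTGGATTTGGGATCGA	candidate
sgZfp017-2	Zfp017	TCAGCCGCGGATCAGGCCCA	candidate
sgZfp017-3	Zfp017	GTACAAGCATCGCCCGAACC	candidate
sgZfp018-1	Zfp018	GCCAGCTTTCGCGACTATAT	candidate
sgZfp018-2	Zfp018	CCCCGCTTCACGCCGTGGTC	candidate
sgZfp018-3	Zfp018	CTCAATAGTCAGGGCTACAG	candidate
sgZfp019-1	Zfp019	TCGTTACTATACCTTGGGTG	candidate
sgZfp019-2	Zfp019	TCTGAACGTATGTTCACTGC	candidate
sgZfp019-3	Zfp019	CACAAGATCTGGTAGTACTA	candidate
sgZfp020-1	Zfp020	ACTTGAGTACCACATGGGGG	candidate
sgZfp020-2	Zfp020	CCGTCACTCTAGCTAGGATG	candidate
sgZfp020-3	Zfp020	TATCACCTAAATCCGACAAG	candidate
sgZfp021-1	Zfp021	TCTAACTTTATGAATCAGAG	candidate
sgZfp021-2	Zfp021	GGTGCCCCGTGAAATACAGT	candidate
sgZfp021-3	Zfp021	CACGTCGACATGAAGTAAGT	candidate
sgZfp022-1	Zfp022	ACACCTCTTTCCTATGGAAC	candidate
sgZfp022-2	Zfp022	GCCCGGAGTACCCATTCCTT	candidate
sgZfp022-3	Zfp022	GGTGCGCTGGCTAAAGGCGG	candidate
sgZfp023-1	Zfp023	AGGTTGATTGCCTACCTCAG	candidate
sgZfp023-2	Zfp023	ATGGCGAGTGTGCTTCGACC	candidate
sgZfp023-3	Zfp023	ACGTGCGGCTCTATGTCACC	candidate
sgZfp024-1	Zfp024	TAGTTCCAAAAAACCCGCTC	candidate
sgZfp024-2	Zfp024	CCAATGTAGCCGCCTCTTAA	candidate
sgZfp024-3	Zfp024	AACCCTTACTGGTGACGCGC	candidate
sgZfp025-1	Zfp025	GACTGCCTTTCAGCGCACTT	candidate
sgZfp025-2	Zfp025	CGCACACCAATCGTTTCCTC	candidate
sgZfp025-3	Zfp025	GTCGATGTTCGCTTAAGCGG	candidate
sgZfp026-1	Zfp026	GGCTCGGGGGCCTTACGAGG	candidate
sgZfp026-2	Zfp026	CTTGGCCAATTTTGGAAATC	candidate
sgZfp026-3	Zfp026	GTTAGGACAATGGTCATCTG	candidate
sgZfp027-1	Zfp027	CGCTCGCATTGAACGAATGC	candidate
sgZfp027-2	Zfp027	ATATCCGAGTGGCCAGAGTT	candidate
sgZfp027-3	Zfp027	AATTCCGGAACATACATAGC	candidate
sgZfp028-1	Zfp028	CGATAGAGTGGAAAGCCTTT	candidate
sgZfp028-2	Zfp028	TATCCTGTTTTAGTCGTCTG	candidate
sgZfp028-3	Zfp028	TTCCGATCGGCCTGGAGCTC	candidate
sgZfp114-1	Zfp114	GGGAGAGCCCCTGGCATACA	candidate
sgZfp114-2	Zfp114	CGGACCTCCACGCATCTACA	candidate
sgZfp114-3	Zfp114	AACCACGGTTGGCTACGCTG	candidate
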