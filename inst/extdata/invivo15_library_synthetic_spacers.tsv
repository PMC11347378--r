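guide_id	gene	spacer	role
sgBcl6-1	Bcl6	TGGGATGCTAGACTTTAAGC	positive_control
sgBcl6-2	Bcl6	ACTAGAAGTCATTCATGCCG	positive_control
sgBcl6-3	Bcl6	GCGTTGATTAGAGGCAGGTT	positive_control
sgBtk-1	Btk	CAATCTTCATGAAGTTCATA	positive_control
sgBtk-2	Btk	AGGCTCTGTCCCTCTCAGCA	positive_control
sgBtk-3	Btk	CGTCGCCTGGCGATATCCAT	positive_control
sgCd3e-1	Cd3e	CGTTGTTTGACGTCGGTGTG	positive_control
sgCd3e-2	Cd3e	CGAAAGCATGCGCTTTCAAA	positive_control
sgCd3e-3	Cd3e	TGCTGAATACTTACCAATCA	positive_control
sgCsf3r-1	Csf3r	ATGACGATAGTTCGCGTTAT	positive_control
sgCsf3r-2	Csf3r	TTAGTAGAGAACATATTCGA	positive_control
sgCsf3r-3	Csf3r	ATAATTCGATAAATGGCATG	positive_control
sgDach1-1	Dach1	GTCGTCTCGGCATAGAACAA	candidate
sgDach1-2	Dach1	GCAAATACACGTTCCAGTGT	candidate
sgDach1-3	Dach1	AATGTCTCTCGACCTCCGGA	candidate
sgEbf1-1	Ebf1	CGTCTGTCCGACAAATTTTG	positive_control
sgEbf1-2	Ebf1	AGAAAGAGGTAACTTTTTTT	positive_control
sgEbf1-3	Ebf1	GACAGCTGATCATCACAAGA	positive_control
sgGfi1-1	Gfi1	CATCCGAGACACTGTTGTCA	positive_control
sgGfi1-2	Gfi1	TATGGGGGACGATGCGTTAC	positive_control
sgGfi1-3	Gfi1	AGTCCGTCACTTCTATGACC	positive_control
sgGfi1b-1	Gfi1b	GCTTTAACCCGCTCTTTCAA	negative_control
sgGfi1b-2	Gfi1b	GAAAGTCCCGGGGCTCGGAA	negative_control
sgGfi1b-3	Gfi1b	ACCTTACACGCTGCTTGTCC	negative_control
sgMllt3-1	Mllt3	TTCATACTTACATCCGTGAC	candidate
sgMllt3-2	Mllt3	GACACTTCATCTAGACCCAT	candidate
sgMllt3-3	Mllt3	CGGAAACTTCACTCGTTCGC	candidate
sgNotch1-1	Notch1	ACATCGAAGTCTGAAAGGAG	positive_control
sgNotch1-2	Notch1	CCTAGAGTGTTGGTGTAAGA	positive_control
sgNotch1-3	Notch1	TTAGGCCCCTTATTTGTTCC	positive_control
sgPax5-1	Pax5	ATTGGAAGGACGGAGTGGCC	positive_control
sgPax5-2	Pax5	AATAGCTTGACGCACTGTAC	positive_control
sgPax5-3	Pax5	TATTGAGGAGCGCTTTCCAC	positive_control
sgRosa26-1	Rosa26	AAATATCGATAGCTCCCGCT	negative_control
sgRosa26-2	Rosa26	CGGTTCGTTGAGAGAGGTCA	negative_control
sgRosa26-3	Rosa26	TCCCAGCGTGAACACAGCGA	negative_control
sgTfdp1-1	Tfdp1	GACGCCTACCGAACTCAATG	candidate
sgTfdp1-2	Tfdp1	TTTCGGCAACCTTCTCCCCA	candidate
sgTfdp1-3	Tfdp1	AATTTCTACTGATCAACACG	candidate
sgUhrf1-1	Uhrf1	CGGGGGGACCTGCTCAAATG	positive_control
sgUhrf1-2	Uhrf1	CGGGGTAGTTCAAAAAATAA	positive_control
sgUhrf1-3	Uhrf1	CTGGCACGTTGGAATATTAG	positive_control
sgZfp114-1	Zfp114	TTACACACCGCTTACAATAT	candidate
sgZfp114-2	Zfp114	GGTACCGATTGCGACGTCCG	candidate
sgZfp114-3	Zfp114	CAGGAGATGGGTCCCCGCTA	candidate
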