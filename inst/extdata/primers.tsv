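name	sequence	direction
8F	AGRGTTYGATYNTGGCTCAG	forward
341F	CCTACGGGNGGCWGCAG	forward
515F	GTGYCAGCMGCCGCGGTAA	forward
U789F	TAGATACCCNSGTAGTCC	forward
967F	CAACGCGAAGAACCTTACC	forward
1099F	GYAACGAGCGCAACCC	forward
357R	CTGCTGCCTYCCGTA	reverse
518R	TTACCGCGGCKGCTGGCAC	reverse
806R	GGACTACNVGGGTWTCTAAT	reverse
926R	CCGYCAATTYMTTTRAGTTT	reverse
1064R	CGACRRCCATGCANCACCT	reverse
1406R	GACGGGCRGTGWGTRCA	reverse
1492R	TACCTTGTTACGACTT	reverse
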