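label	region	forward	reverse	layout	read_length
V1 SE 100 bp	V1	8F	357R	SE	100
V1 SE 150 bp	V1	8F	357R	SE	150
V1 SE 300 bp	V1	8F	357R	SE	300
V1-V2 PE 250 bp	V1-V2	8F	357R	PE	250
V1-V3 PE 300 bp	V1-V3	8F	518R	PE	300
V3 PE 150 bp	V3	341F	518R	PE	150
V3 SE 100 bp	V3	341F	806R	SE	100
V3 SE 150 bp	V3	341F	806R	SE	150
V3 SE 300 bp	V3	341F	806R	SE	300
V3-V4 PE 250 bp	V3-V4	341F	806R	PE	250
V3-V5 PE 300 bp	V3-V5	341F	926R	PE	300
V4 PE 150 bp	V4	515F	806R	PE	150
V4 SE 100 bp	V4	515F	926R	SE	100
V4 SE 150 bp	V4	515F	926R	SE	150
V4 SE 300 bp	V4	515F	926R	SE	300
V4-V5 PE 250 bp	V4-V5	515F	926R	PE	250
V4-V6 PE 300 bp	V4-V6	515F	1064R	PE	300
V5 PE 100 bp	V5	U789F	926R	PE	100
V5 SE 100 bp	V5	U789F	1064R	SE	100
V5 SE 150 bp	V5	U789F	1064R	SE	150
V5 SE 300 bp	V5	U789F	1064R	SE	300
V5-V6 PE 150 bp	V5-V6	U789F	1064R	PE	150
V6 PE 100 bp	V6	967F	1064R	PE	100
V6 SE 100 bp	V6	967F	1406R	SE	100
V6 SE 150 bp	V6	967F	1406R	SE	150
V6 SE 300 bp	V6	967F	1406R	SE	300
V6-V8 PE 250 bp	V6-V8	967F	1406R	PE	250
V7 SE 100 bp	V7	1099F	1406R	SE	100
V7 SE 150 bp	V7	1099F	1406R	SE	150
V7 SE 300 bp	V7	1099F	1406R	SE	300
V7-V8 PE 250 bp	V7-V8	1099F	1406R	PE	250
V7-V9 PE 250 bp	V7-V9	1099F	1492R	PE	250
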