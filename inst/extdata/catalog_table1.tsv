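# alpha-synuclein amyloid structures: accession, analyzed chain, fragment.
# Proto-/super-fibril chain groupings are deposition-specific; declare them
# by editing the chains column (groups separated by '+', chains by ',').
structure	chains	fragment	levels
6CU8	E	43-83	chain
6CU7	D	43-83	chain
6L1T	C	1-100	chain
6RTB	C	36-98	chain
6SST	C	14-96	chain
6SSX	C	14-97	chain
6RT0	A	37-97	chain
6UFR	A	36-99	chain
7L7H	B	61-98	chain
7NCI	C	37-97	chain
7NCJ	C	14-96	chain
7NCA	D	37-97	chain
7NCG	A	14-91	chain
7NCH	C	14-91	chain
7NCK	C	9-93	chain
7LC9	A	46-96	chain
7LC9	C	46-98	chain
6A6B	C	38-97	chain
6L4S	A	46-96	chain
6XYO	B	21-99	chain
6XYP	B	36-99	chain
6XYP	A	14-94	chain
6XYO	A	14-94	chain
6H6B	E	37-97	chain
6FLT	E	38-95	chain
6OSL	E	37-96	chain
6OSJ	E	39-97	chain
6OSM	E	38-95	chain
7E0F	B	37-99	chain
6LRQ	B	37-99	chain
6PEO	A	36-99	chain
6PES	A	14-94	chain
6XYQ	B	36-99	chain
6XYQ	A	14-94	chain
7C1D	A	37-97	chain
2N0A	B	1-140	chain
2N0A	B	38-100	chain
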