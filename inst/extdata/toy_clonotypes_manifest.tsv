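row	cdr3_aa	keep	reason
1	CASSLGGNTGKLIF	TRUE	functional, count 12 >= 3
2	CAASETSGSWQLIF	FALSE	count 2 < 3
3	CAVSNTNKVVF	TRUE	boundary: count 3 retained
4	CAMR*GSALGRLHF	FALSE	stop codon sentinel
5	CALG_NTEGADRLTF	FALSE	frameshift sentinel
6	CAASRNSGTYQRF	FALSE	count 1 < 3
7	CAVSAGGYKVVF	TRUE	functional, count 55 >= 3
8	CAVSAGGYKVVF	TRUE	lower case upper-cased on ingest, count 4 >= 3
9	CILRVGATGGNNKLTF	TRUE	boundary: count 3 retained
10	CAASMNYNQGKLIF	FALSE	count 0 < 3
11	CAVSDNYAQGLTF	TRUE	functional, count 6 >= 3
12	CAVSAGGYKVVF	TRUE	duplicate clonotype of row 7, collapses to one
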