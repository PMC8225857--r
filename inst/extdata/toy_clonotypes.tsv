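Count	CDR3.amino.acid.sequence	V.segments	J.segments
12	CASSLGGNTGKLIF	TRAV6-7,TRAV6-6	TRAJ33
2	CAASETSGSWQLIF	TRAV14-1	TRAJ22
3	CAVSNTNKVVF	TRAV3-3	TRAJ34
10	CAMR*GSALGRLHF	TRAV16	TRAJ18
8	CALG_NTEGADRLTF	TRAV13-1	TRAJ45
1	CAASRNSGTYQRF	TRAV14-2	TRAJ13
55	CAVSAGGYKVVF	TRAV3-3	TRAJ12
4	cavsagGYKVVF	TRAV9-1	TRAJ12
3	CILRVGATGGNNKLTF	TRAV26	TRAJ56
0	CAASMNYNQGKLIF	TRAV14-3	TRAJ23
6	CAVSDNYAQGLTF	TRAV3-3	TRAJ26
7	CAVSAGGYKVVF	TRAV3-3	TRAJ12
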