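position	gene	sample	ref	alt	alt_reads	total_reads
4105	ND2	AUS4	C	A	2	167
5690	COI	AUS4	T	A	2	74
6245	COI	AUS4	C	A	2	153
6245	COI	AUS5	C	A	3	171
7561	COII	AUS5	G	T	2	109
10220	ND3	AUS5	A	G	2	151
11804	ND4	AUS4	G	T	2	151
12505	ND5	AUS5	T	C	2	191
12764	ND5	AUS5	C	T	2	108
12962	ND5	AUS5	G	T	2	85
15735	Cytb	AUS4	T	C	44	93
15735	Cytb	AUS5	T	C	35	90
15735	Cytb	AUS7	T	C	15	53
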