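position	class	chloro_t1	mito_t1	chloro_t2	mito_t2	in_gene	reported_origin
35570	SNP	Ref	Alt	Ref	Ref	yes	Mito
36347	DEL	Ref	Alt	Ref	Ref	yes	Mito
36942	SNP	Ref	Ref	Alt	Ref	no	Chloro
37257	SNP	Ref	Alt	Alt	Alt	no	Chloro
37813	SNP	AltSome	Ref	Ref	Ref	no	Chloro
38753	DEL	Ref	Ref	Ref	Alt	yes	Mito
38975	SNP	Ref	Ref	Alt	Ref	no	Chloro
39429	SNP	Ref	Alt	Ref	Ref	yes	Mito
40061	SNP	Ref	Alt	Ref	Ref	yes	Mito
40544	SNP	Ref	Alt	Ref	Ref	yes	Mito
41243	SNP	Ref	Alt	Alt	Alt	yes	Chloro
41716	SNP	Ref	Ref	Ref	Alt	yes	Mito
41718	SNP	Ref	Ref	Ref	Alt	yes	Mito
42587	SNP	Ref	Ref	Alt	Ref	yes	Chloro
43559	SNP	Ref	Ref	Ref	Alt	no	Mito
44059	INS	Ref	Alt	Alt	Alt	no	Chloro
44235	DEL	Ref	Alt	Ref	Ref	no	Mito
44302	SNP	Ref	Alt	Ref	Ref	no	Mito
44552	SNP	Ref	Ref	Ref	Alt	no	Mito
44762	DEL	Ref	Ref	Ref	Alt	no	Mito
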