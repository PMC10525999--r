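chromosome	position	variant_type	gene	region	product
LS1	54113	Indel	nad7	Intron	NADH dehydrogenase subunit 7
LS2	2368	SNP	matR	Exon	maturase
LS2	35483	Indel	nad4	Intron	NADH dehydrogenase subunit 4
LS2	37645	SNP	nad4	Intron	NADH dehydrogenase subunit 4
LS2	39597	Indel	nad4	Intron	NADH dehydrogenase subunit 4
LS2	40927	SNP	nad4	Intron	NADH dehydrogenase subunit 4
LS2	41027	Indel	nad4	Intron	NADH dehydrogenase subunit 4
LS2	56879	SNP	rps3	Intron	ribosomal protein S3
LS2	69748	SNP	nad2	Intron	NADH dehydrogenase subunit 2
LS2	71388	Indel	nad2	Intron	NADH dehydrogenase subunit 2
LS2	71633	Indel	nad2	Intron	NADH dehydrogenase subunit 2
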