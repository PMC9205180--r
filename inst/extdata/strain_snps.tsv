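snp_id	gene	exon	offset	strainA_base	strainB_base	placement
rs29176517	IGHM	CH1	291	g	a	reported
rs45969375	IGHG2B	CH1	99	c	t	synthetic
rs49934817	IGHG2B	CH2	60	c	t	synthetic
rs45822066	IGHG2B	CH2	150	c	a	synthetic
rs46899601	IGHG2B	CH2	240	c	g	synthetic
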