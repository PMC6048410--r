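Cytotoxic cells	synthetic toy marker set	PRF1	GZMA	CD8A
Regulatory T cell	synthetic toy marker set	FOXP3	CCR7
B cells	synthetic toy marker set	MS4A1
NK cells	synthetic toy marker set	NCAM1	PRF1
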