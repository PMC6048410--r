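gene	P01	P02	P03	P04
PRF1	4.0	1.2	9.5	0.4
GZMA	9.0	1.1	8.7	0.5
IFNG	6.2	0.9	7.4	0.3
VEGFA	2.1	8.8	1.5	9.2
CD8A	7.5	1.4	8.1	0.6
FOXP3	2.2	2.5	3.1	2.0
CCR7	3.3	1.8	4.2	1.1
MS4A1	1.9	2.2	2.4	2.6
NCAM1	2.8	1.0	3.5	0.8
ALDOA	5.0	5.2	4.9	5.1
GAPDH	9.9	9.7	10.1	9.8
ACTB	8.8	8.9	9.0	8.7
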