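sample_id	os_days	event	side
P01	1450	0	cecum
P02	320	1	rectum
P03	2800	0	sigmoid
P04	510	1	transverse
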