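taxon_id	samp01	samp02	samp03	samp04	samp05	samp06
otu01	27	23	33	15	28	25
otu02	19	28	20	25	33	30
otu03	15	21	24	34	22	27
otu04	32	20	30	33	24	20
otu05	30	12	24	25	18	25
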