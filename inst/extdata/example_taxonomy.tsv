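taxon_id	taxonomy
otu01	Bacteria;Firmicutes;Bacilli
otu02	Bacteria;Firmicutes;Clostridia
otu03	Bacteria;Bacteroidetes;Bacteroidia
otu04	Bacteria;Bacteroidetes
otu05	Bacteria;Proteobacteria;Gammaproteobacteria
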