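sample_id	group
samp01	control
samp02	control
samp03	control
samp04	treated
samp05	treated
samp06	treated
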