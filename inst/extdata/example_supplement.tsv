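node_id	kind	value
MI:0006	synonym	anti bait immunoprecipitation
MI:0440	synonym	radioligand binding
MI:0006	keyword	coimmunoprecipitation
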