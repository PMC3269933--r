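term	mi	chi2
two hybrid	0.439	1225.574
immunoprecipitation	0.437	1110.124103
hybrid	0.398	1041.587496
yeast two	0.348	1061.789
diffraction	0.263	1142.337
resonance	0.236	969.286
crystallography	0.182	751.011
x ray	0.176	622.764
yeast	0.173	402.283
gal4	0.168	576.122
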