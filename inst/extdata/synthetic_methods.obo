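format-version: 1.2
! Synthetic miniature interaction-detection-methods ontology, hand-written
! for tests and examples. Node IDs follow the PSI-MI accession style but
! this file is NOT the PSI-MI ontology.

[Term]
id: MI:0018
name: two hybrid
synonym: "2 hybrid" EXACT []
synonym: "classical two hybrid" EXACT []
synonym: "yeast two hybrid" RELATED []

[Term]
id: MI:0006
name: anti bait coimmunoprecipitation
synonym: "anti bait coip" EXACT []

[Term]
id: MI:0007
name: anti tag coimmunoprecipitation
synonym: "anti tag coip" EXACT []

[Term]
id: MI:0096
name: pull down

[Term]
id: MI:0440
name: saturation binding

[Term]
id: MI:0114
name: x-ray crystallography
synonym: "x-ray diffraction" RELATED []

[Term]
id: MI:9999
name: retired method
is_obsolete: true
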