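species	rate
Bombyx mori	4.1e-09
Drosophila melanogaster	2.8e-09
Heliconius melpomene	2.9e-09
Apis mellifera	3.4e-09
Bombus terrestris	3.6e-09
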