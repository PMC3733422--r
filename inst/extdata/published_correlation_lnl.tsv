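trait_pair	lnl_independent	lnl_dependent	lnl_difference	p_published
Habitat x ANG	-37.312	-31.123	-6.190	0.0147
Habitat x Cornea	-37.497	-33.551	-4.253	0.0747
Habitat x Autogenic-photophore	-90.043	-79.445	10.598	0.0003
Habitat x Bacteriogenic-photophore	-51.143	-47.450	3.693	0.1169
Habitat x Branchial canal	-38.952	-38.915	-0.075	0.9973
Habitat x Right oviduct	-37.813	-34.861	-2.952	0.2062
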