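name	core	klass	factor
Otx-strict	GGATTA	strict	Otx
Otx-canonical	GATTA	canonical	Otx
Otx-non-canonical	GHATTA	non-canonical	Otx
Fox-canonical	AAACA	canonical	Fox
Fox-non-canonical	AACA	non-canonical	Fox
SBE	AGAC	canonical	Smad
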