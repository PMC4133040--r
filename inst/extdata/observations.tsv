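lineage	perturbations	fgf_input	marker	expected	provenance
b		TRUE	Msxb	ON	Fig 2Bi
b		TRUE	Delta2	ON	Fig 3B
b		TRUE	Chordin	ON	Fig 3C
b		TRUE	Epi	OFF	Fig S1C
b		TRUE	NodalL	ON	Fig S3A-i
a		TRUE	Dmrt1	ON	Fig 3D
a		TRUE	Msxb	OFF	Fig 3A
a		FALSE	Dmrt1	OFF	Fig 3D
b	mek_block	TRUE	Msxb	OFF	Fig 2Biv
b	mek_block	TRUE	Delta2	OFF	Fig S1E
b	mek_block	TRUE	Chordin	OFF	Fig S1F
b	mek_block	TRUE	Epi	ON	Fig S1G
a	mek_block	TRUE	Epi	ON	Fig S1G
b	alk_block	TRUE	Msxb	OFF	Fig 2Bvii
b	alk_block	TRUE	Delta2	OFF	Fig S1I
b	alk_block	TRUE	Chordin	OFF	Fig S1J
b	alk_block	TRUE	Epi	OFF	Fig S1K
b	alk_block	TRUE	NodalL	OFF	Fig S3A (autoregulation)
b	lefty_oe	TRUE	Msxb	OFF	Fig 3I
b	lefty_oe	TRUE	Delta2	OFF	Fig 3J
b	lefty_oe	TRUE	Chordin	OFF	Fig 3K
a	lefty_oe	TRUE	Dmrt1	ON	Fig 3L
b	lefty_oe	TRUE	NodalL	OFF	Fig S3A-iv
b	fgf_oe	FALSE	Msxb	ON	Fig 3E
b	fgf_oe	FALSE	Delta2	ON	Fig 3F
b	fgf_oe	FALSE	Chordin	ON	Fig 3G
a	fgf_oe	FALSE	Dmrt1	ON	Fig 3H
a	fgf_oe	FALSE	Msxb	OFF	Fig 3E
b	fgf_oe,lefty_oe	FALSE	Msxb	OFF	Fig 3M
b	fgf_oe,lefty_oe	FALSE	Delta2	OFF	Fig 3N
b	fgf_oe,lefty_oe	FALSE	Chordin	OFF	Fig 3O
a	fgf_oe,lefty_oe	FALSE	Dmrt1	ON	Fig 3P
a	nodal_oe	TRUE	Msxb	ON	Fig 3Q
a	nodal_oe	TRUE	Delta2	ON	Fig 3R
a	nodal_oe	TRUE	Chordin	ON	Fig 3S
b	nodal_oe	TRUE	Chordin	ON	Fig 3S
a	nodal_oe	TRUE	Dmrt1	OFF	Fig 3T
b	nodal_oe	FALSE	Msxb	OFF	Fig 3Q (no ectopic)
a	fgf_oe,nodal_oe	FALSE	Msxb	ON	Fig 3U
a	fgf_oe,nodal_oe	FALSE	Delta2	ON	Fig 3V
a	fgf_oe,nodal_oe	FALSE	Dmrt1	OFF	Fig 3X
b	otx_mo	TRUE	Msxb	OFF	Fig 4C
b	otx_mo	TRUE	Delta2	OFF	Fig 4F
b	otx_hd_enr	TRUE	Msxb	OFF	Fig S4B
b	otx_hd_enr	TRUE	Delta2	OFF	Fig S4D
b	otx_hd_enr	TRUE	Epi	OFF	Fig S4F
b	otx_hd_enr	TRUE	NodalL	OFF	Fig S3A-iii
b	otx_oe	TRUE	Msxb	ON	Fig 4B
a	otx_oe	TRUE	Msxb	ON	Fig 4B
a	otx_oe	TRUE	Delta2	ON	Fig 4E
b	otx_oe	TRUE	NodalL	ON	Fig S3A-ii
b	otx_oe,lefty_oe	TRUE	Msxb	ON	Fig S3B-iv
a	otx_oe,lefty_oe	TRUE	Delta2	ON	Fig S3B-viii
a	nodal_oe,otx_hd_enr	TRUE	Msxb	OFF	Fig S3C
a	nodal_oe,otx_hd_enr	TRUE	Delta2	OFF	Fig S3C
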