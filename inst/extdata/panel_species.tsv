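# Restricted adulterant panel: 20 congeneric species with selection flags
# (rel = close relative in Section Hypericum; mpns = medicinal-plant listing
# with at least one reference; cult = horticultural/ornamental listing;
# adult = reported adulterant of the target) and published clade placements.
# cbc_vs_target = published CBC count of the species' ITS2 structure vs the
# target species (NA where no structure was modelled).
species	attribution	section	robson_clade	meseguer_clade	rel	mpns	cult	adult	cbc_vs_target
H. acmosepalum	N.Robson	Ascyreia	3	D	FALSE	FALSE	FALSE	TRUE	1
H. androsaemum	L.	Androsaemum	5	C	FALSE	TRUE	TRUE	TRUE	2
H. ascyron	L.	Roscyna	7	D	FALSE	TRUE	FALSE	TRUE	5
H. athoum	Boiss. & Orph	Adenosepalum	27	unknown	FALSE	FALSE	TRUE	FALSE	NA
H. attenuatum	Fisch. ex Choisy	Hypericum	9	E	TRUE	FALSE	FALSE	FALSE	0
H. barbatum	Jacq.	Drosocarpium	13	E	FALSE	FALSE	FALSE	TRUE	0
H. calycinum	L.	Ascyreia	3	D	FALSE	TRUE	TRUE	FALSE	1
H. crux-andreae	(L.) Crantz	Myriandra	20	B	FALSE	TRUE	FALSE	TRUE	4
H. delphicum	Boiss. & Heldr.	Adenosepalum	27	E	FALSE	FALSE	FALSE	FALSE	0
H. elegans	Stephan ex Willd.	Hypericum	9	unknown	TRUE	TRUE	FALSE	FALSE	NA
H. hirsutum	L.	Taeniocarpium	18	E	FALSE	FALSE	FALSE	TRUE	0
H. japonicum	Thunb.	Trigynobrathys	30	B	FALSE	TRUE	TRUE	FALSE	5
H. kouytchense	H.Lev	Ascyreia	3	D	FALSE	FALSE	TRUE	FALSE	1
H. maculatum	Crantz	Hypericum	9	E	TRUE	TRUE	FALSE	TRUE	0
H. montanum	L.	Adenosepalum	27	E	FALSE	FALSE	FALSE	TRUE	0
H. olympicum	L.	Oligostema	14	E	FALSE	FALSE	TRUE	FALSE	0
H. patulum	Thunb.	Ascyreia	3	D	FALSE	TRUE	TRUE	TRUE	1
H. perforatum	L.	Hypericum	9	E	FALSE	TRUE	TRUE	FALSE	0
H. tetrapterum	Fr.	Hypericum	9	E	TRUE	TRUE	TRUE	TRUE	0
H. undulatum	Schousb. ex Willd.	Hypericum	9	E	TRUE	FALSE	FALSE	TRUE	0
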