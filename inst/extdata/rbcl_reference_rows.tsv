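# Published rbcL haplotype reference rows (panel map + reference-sample
# assignments), dots resolved against the consensus C,C,A,A,A,A,A at
# positions 66,180,263,300,372,378,492. type_label as printed (ASCII
# hyphen for the intermediate).
row_id	source	type_label	s66	s180	s263	s300	s372	s378	s492
H. perforatum (panel)	panel_map	1p	T	T	T	G	C	A	A
H. maculatum (panel)	panel_map	1	C	T	A	G	C	A	A
H. tetrapterum (panel)	panel_map	1	C	T	A	G	C	A	A
H. undulatum (panel)	panel_map	1	C	T	A	G	C	A	A
H. montanum (panel)	panel_map	1	C	T	A	G	C	A	A
H. hirsutum (panel)	panel_map	1	C	C	A	G	C	A	A
H. androsaemum (panel)	panel_map	2	C	C	A	A	A	G	T
H. ascyron (panel)	panel_map	2	C	C	A	A	A	G	T
H. calycinum (panel)	panel_map	2	C	C	A	A	A	G	T
H. crux-andreae (panel)	panel_map	2	C	C	A	A	A	G	T
H. japonicum (panel)	panel_map	2	C	C	A	A	A	G	T
H. perforatum 13876	reference_samples	1p	T	T	T	G	C	A	A
H. delphicum 13938	reference_samples	1	C	T	A	G	C	A	A
H. montanum A12F	reference_samples	1	C	T	A	G	C	G	A
H. kouytchense 13866	reference_samples	1-2	C	C	A	A	A	A	A
H. patulum 13908	reference_samples	1-2	C	C	A	A	A	A	A
H. perforatum 13921	reference_samples	1-2	C	C	A	A	A	A	A
H. perforatum 13932	reference_samples	1-2	C	C	A	A	A	A	A
H. androsaemum 13854	reference_samples	1-2	C	C	A	A	A	A	A
H. ascyron 13993	reference_samples	2	C	C	A	A	A	G	T
H. athoum 13923	reference_samples	2	C	C	A	A	A	G	T
H. calycinum 13929	reference_samples	2	C	C	A	A	A	G	T
H. maculatum 13896	reference_samples	2	C	C	A	A	A	G	T
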