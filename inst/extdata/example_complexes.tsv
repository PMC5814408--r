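ComplexID	ComplexName	subunits(UniProt IDs)
181	20S proteasome (synthetic membership excerpt)	P25786;P25787;P25788;P25789;P28066;P60900;O14818
193	19S regulatory particle (synthetic membership excerpt)	P62191;P35998;P17980;P43686;P62195;P62333
2397	Chaperonin CCT (synthetic membership excerpt)	P17987;P78371;P49368;P50991;P48643;P40227;Q99832;P50990
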