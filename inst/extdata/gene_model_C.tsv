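# locus: C
# Schematic class I C-locus model: only I3 (588 bp) and E8 (5 bp) are
# published anchors; other segment lengths are HLA-like placeholders.
label	kind	length
E1	exon	73
I1	intron	130
E2	exon	270
I2	intron	241
E3	exon	276
I3	intron	588
E4	exon	276
I4	intron	102
E5	exon	117
I5	intron	444
E6	exon	33
I6	intron	142
E7	exon	48
I7	intron	170
E8	exon	5
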