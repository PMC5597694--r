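# Published summary grid of distinct-allele counts by scope, locus and
# collapse level (NA = locus not present in that scope).
scope	locus	level	count
bonobo	A	full	13
bonobo	B	full	13
bonobo	C	full	11
bonobo	AL	full	NA
bonobo	A	coding	11
bonobo	B	coding	13
bonobo	C	coding	10
bonobo	AL	coding	NA
bonobo	A	protein	11
bonobo	B	protein	13
bonobo	C	protein	10
bonobo	AL	protein	NA
chimpanzee	A	full	30
chimpanzee	B	full	41
chimpanzee	C	full	29
chimpanzee	AL	full	11
chimpanzee	A	coding	25
chimpanzee	B	coding	39
chimpanzee	C	coding	26
chimpanzee	AL	coding	3
chimpanzee	A	protein	25
chimpanzee	B	protein	39
chimpanzee	C	protein	25
chimpanzee	AL	protein	3
chimpanzee_central	A	full	20
chimpanzee_central	B	full	26
chimpanzee_central	C	full	20
chimpanzee_central	AL	full	8
chimpanzee_central	A	coding	18
chimpanzee_central	B	coding	25
chimpanzee_central	C	coding	17
chimpanzee_central	AL	coding	3
chimpanzee_central	A	protein	18
chimpanzee_central	B	protein	25
chimpanzee_central	C	protein	16
chimpanzee_central	AL	protein	3
combined	A	full	43
combined	B	full	54
combined	C	full	40
combined	AL	full	11
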