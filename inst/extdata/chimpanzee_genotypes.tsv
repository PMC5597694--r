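# Transcription of the published genotype table for 30 chimpanzees
# (6 P.t.s., 4 P.t.v., 20 P.t.t.); one row per individual x locus,
# single entries are homozygous calls, "-" at Patr-AL = locus absent.
individual	taxon	locus	allele1	allele2
Bihati	P.t.s.	Patr-A	Patr-A*15:01:01:01	Patr-A*08:01:01:01
Bihati	P.t.s.	Patr-B	Patr-B*07:04	Patr-B*23:06
Bihati	P.t.s.	Patr-C	Patr-C*07:02	Patr-C*09:05
Bihati	P.t.s.	Patr-AL	Patr-AL*01:01:01:04
Cleo	P.t.s.	Patr-A	Patr-A*22:01	Patr-A*08:01:01:01
Cleo	P.t.s.	Patr-B	Patr-B*38:02	Patr-B*23:04
Cleo	P.t.s.	Patr-C	Patr-C*02:05	Patr-C*09:05
Cleo	P.t.s.	Patr-AL	Patr-AL*01:01:01:06
Diana	P.t.s.	Patr-A	Patr-A*27:01	Patr-A*15:01:01:01
Diana	P.t.s.	Patr-B	Patr-B*22:04	Patr-B*22:05
Diana	P.t.s.	Patr-C	Patr-C*17:02	Patr-C*03:07
Diana	P.t.s.	Patr-AL	Patr-AL*01:01:01:08
Maya	P.t.s.	Patr-A	Patr-A*15:01:01:02	Patr-A*13:01:01:02
Maya	P.t.s.	Patr-B	Patr-B*23:05	Patr-B*33:01:01:02
Maya	P.t.s.	Patr-C	Patr-C*09:02:01:01	Patr-C*09:05
Maya	P.t.s.	Patr-AL	Patr-AL*01:01:01:08
Tongo	P.t.s.	Patr-A	Patr-A*15:01:01:01	Patr-A*08:01:01:01
Tongo	P.t.s.	Patr-B	Patr-B*30:02	Patr-B*22:03
Tongo	P.t.s.	Patr-C	Patr-C*03:05	Patr-C*09:01:01:04
Tongo	P.t.s.	Patr-AL	Patr-AL*01:01:01:04
Trixie	P.t.s.	Patr-A	Patr-A*15:02
Trixie	P.t.s.	Patr-B	Patr-B*06:03	Patr-B*07:05
Trixie	P.t.s.	Patr-C	Patr-C*11:01:02	Patr-C*09:02:01:02
Trixie	P.t.s.	Patr-AL	Patr-AL*01:02
Alice	P.t.v.	Patr-A	Patr-A*09:01
Alice	P.t.v.	Patr-B	Patr-B*36:01	Patr-B*01:01
Alice	P.t.v.	Patr-C	Patr-C*15:01	Patr-C*04:01
Alice	P.t.v.	Patr-AL	Patr-AL*01:01:01:01
Berta	P.t.v.	Patr-A	Patr-A*03:02	Patr-A*09:01
Berta	P.t.v.	Patr-B	Patr-B*20:01:02	Patr-B*01:01
Berta	P.t.v.	Patr-C	Patr-C*12:01	Patr-C*04:01
Berta	P.t.v.	Patr-AL	Patr-AL*01:01:01:01
Cindy	P.t.v.	Patr-A	Patr-A*05:01	Patr-A*04:04
Cindy	P.t.v.	Patr-B	Patr-B*13:01
Cindy	P.t.v.	Patr-C	Patr-C*03:01
Cindy	P.t.v.	Patr-AL	Patr-AL*01:01:01:01
Linda	P.t.v.	Patr-A	Patr-A*06:02	Patr-A*03:01
Linda	P.t.v.	Patr-B	Patr-B*04:02	Patr-B*24:01
Linda	P.t.v.	Patr-C	Patr-C*16:01	Patr-C*09:01:01:04
Linda	P.t.v.	Patr-AL	-
Agnagui	P.t.t.	Patr-A	Patr-A*25:01:01:01	Patr-A*17:01:01:01
Agnagui	P.t.t.	Patr-B	Patr-B*11:03	Patr-B*12:03
Agnagui	P.t.t.	Patr-C	Patr-C*03:02:02:01	Patr-C*15:02
Agnagui	P.t.t.	Patr-AL	-
Bailele	P.t.t.	Patr-A	Patr-A*26:01	Patr-A*17:04
Bailele	P.t.t.	Patr-B	Patr-B*06:03	Patr-B*18:01
Bailele	P.t.t.	Patr-C	Patr-C*11:01:02	Patr-C*09:01:01:03
Bailele	P.t.t.	Patr-AL	Patr-AL*01:01:01:02
Bayokele	P.t.t.	Patr-A	Patr-A*10:01	Patr-A*18:01
Bayokele	P.t.t.	Patr-B	Patr-B*11:03	Patr-B*22:01
Bayokele	P.t.t.	Patr-C	Patr-C*15:02	Patr-C*09:02:01:01
Bayokele	P.t.t.	Patr-AL	Patr-AL*01:01:01:03
Bimangou	P.t.t.	Patr-A	Patr-A*13:01:01:01	Patr-A*17:04
Bimangou	P.t.t.	Patr-B	Patr-B*07:02	Patr-B*11:04
Bimangou	P.t.t.	Patr-C	Patr-C*07:03	Patr-C*09:01:01:04
Bimangou	P.t.t.	Patr-AL	Patr-AL*01:01:01:05
Botsomi	P.t.t.	Patr-A	Patr-A*18:01
Botsomi	P.t.t.	Patr-B	Patr-B*07:03	Patr-B*35:02
Botsomi	P.t.t.	Patr-C	Patr-C*07:03	Patr-C*03:02:02:02
Botsomi	P.t.t.	Patr-AL	-
Casimir	P.t.t.	Patr-A	Patr-A*27:01	Patr-A*08:01:01:01
Casimir	P.t.t.	Patr-B	Patr-B*22:04	Patr-B*30:02
Casimir	P.t.t.	Patr-C	Patr-C*03:07	Patr-C*09:01:01:04
Casimir	P.t.t.	Patr-AL	Patr-AL*01:01:01:06
Castro	P.t.t.	Patr-A	Patr-A*13:01:01:01	Patr-A*25:01:01:02
Castro	P.t.t.	Patr-B	Patr-B*22:07	Patr-B*06:03
Castro	P.t.t.	Patr-C	Patr-C*11:01:02	Patr-C*04:02
Castro	P.t.t.	Patr-AL	Patr-AL*01:01:01:05
Chinoc	P.t.t.	Patr-A	Patr-A*15:01:01:01
Chinoc	P.t.t.	Patr-B	Patr-B*22:06
Chinoc	P.t.t.	Patr-C	Patr-C*13:03
Chinoc	P.t.t.	Patr-AL	Patr-AL*01:01:01:07
Clara_T	P.t.t.	Patr-A	Patr-A*16:01	Patr-A*17:01:01:02
Clara_T	P.t.t.	Patr-B	Patr-B*40:01:01:01	Patr-B*22:06
Clara_T	P.t.t.	Patr-C	Patr-C*03:02:02:02	Patr-C*03:02:02:01
Clara_T	P.t.t.	Patr-AL	Patr-AL*01:01:01:06	Patr-AL*01:01:01:05
Dzeke	P.t.t.	Patr-A	Patr-A*25:01:01:01	Patr-A*12:01
Dzeke	P.t.t.	Patr-B	Patr-B*11:03	Patr-B*23:01:02
Dzeke	P.t.t.	Patr-C	Patr-C*15:02	Patr-C*10:02
Dzeke	P.t.t.	Patr-AL	-
Elikia	P.t.t.	Patr-A	Patr-A*17:01:01:01	Patr-A*17:04
Elikia	P.t.t.	Patr-B	Patr-B*11:03	Patr-B*18:01
Elikia	P.t.t.	Patr-C	Patr-C*15:02	Patr-C*09:01:01:04
Elikia	P.t.t.	Patr-AL	-
Fan_Tuek	P.t.t.	Patr-A	Patr-A*03:06	Patr-A*13:01:01:01
Fan_Tuek	P.t.t.	Patr-B	Patr-B*22:06	Patr-B*11:02
Fan_Tuek	P.t.t.	Patr-C	Patr-C*03:02:01	Patr-C*13:03
Fan_Tuek	P.t.t.	Patr-AL	Patr-AL*01:04
Gao	P.t.t.	Patr-A	Patr-A*03:05	Patr-A*15:01:01:01
Gao	P.t.t.	Patr-B	Patr-B*19:03	Patr-B*40:01:01:01
Gao	P.t.t.	Patr-C	Patr-C*03:02:02:02	Patr-C*13:03
Gao	P.t.t.	Patr-AL	Patr-AL*01:01:01:09	Patr-AL*01:01:01:07
Golfi	P.t.t.	Patr-A	Patr-A*26:01	Patr-A*18:01
Golfi	P.t.t.	Patr-B	Patr-B*40:01:01:02	Patr-B*40:02
Golfi	P.t.t.	Patr-C	Patr-C*03:02:02:01
Golfi	P.t.t.	Patr-AL	Patr-AL*01:01:01:02
Grand_Maitre	P.t.t.	Patr-A	Patr-A*03:07	Patr-A*15:03
Grand_Maitre	P.t.t.	Patr-B	Patr-B*23:07	Patr-B*11:03
Grand_Maitre	P.t.t.	Patr-C	Patr-C*15:02	Patr-C*17:01
Grand_Maitre	P.t.t.	Patr-AL	Patr-AL*01:02
Imphondo	P.t.t.	Patr-A	Patr-A*16:01	Patr-A*03:07
Imphondo	P.t.t.	Patr-B	Patr-B*35:02	Patr-B*21:02
Imphondo	P.t.t.	Patr-C	Patr-C*09:04	Patr-C*13:04
Imphondo	P.t.t.	Patr-AL	Patr-AL*01:01:01:05
Loufoumbou	P.t.t.	Patr-A	Patr-A*17:01:01:01	Patr-A*08:02
Loufoumbou	P.t.t.	Patr-B	Patr-B*19:04	Patr-B*21:01
Loufoumbou	P.t.t.	Patr-C	Patr-C*09:04	Patr-C*13:01
Loufoumbou	P.t.t.	Patr-AL	Patr-AL*01:01:01:05
Lufino	P.t.t.	Patr-A	Patr-A*08:01:01:02	Patr-A*18:01
Lufino	P.t.t.	Patr-B	Patr-B*23:02	Patr-B*33:01:01:01
Lufino	P.t.t.	Patr-C	Patr-C*03:02:02:01	Patr-C*13:03
Lufino	P.t.t.	Patr-AL	Patr-AL*01:01:01:06
Marcelle	P.t.t.	Patr-A	Patr-A*18:01
Marcelle	P.t.t.	Patr-B	Patr-B*23:02	Patr-B*06:02
Marcelle	P.t.t.	Patr-C	Patr-C*03:06	Patr-C*03:02:02:01
Marcelle	P.t.t.	Patr-AL	-
Moka	P.t.t.	Patr-A	Patr-A*18:01
Moka	P.t.t.	Patr-B	Patr-B*33:01:01:01	Patr-B*11:03
Moka	P.t.t.	Patr-C	Patr-C*15:02	Patr-C*13:03
Moka	P.t.t.	Patr-AL	-
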