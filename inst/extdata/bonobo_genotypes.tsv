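# Transcription of the published genotype table for 21 bonobos;
# one row per individual x locus, single entries are homozygous calls.
# The A-like locus was never observed in bonobos: no Papa-AL rows.
individual	taxon	locus	allele1	allele2
Api	bonobo	Papa-A	Papa-A*03:06	Papa-A*03:03:01:02
Api	bonobo	Papa-B	Papa-B*01:03	Papa-B*07:01:02
Api	bonobo	Papa-C	Papa-C*04:01	Papa-C*03:02
Bandundu	bonobo	Papa-A	Papa-A*05:03
Bandundu	bonobo	Papa-B	Papa-B*07:01:02
Bandundu	bonobo	Papa-C	Papa-C*03:02
Bili_L	bonobo	Papa-A	Papa-A*06:03:01:01	Papa-A*08:03
Bili_L	bonobo	Papa-B	Papa-B*02:02	Papa-B*15:01
Bili_L	bonobo	Papa-C	Papa-C*03:01:01:03	Papa-C*06:01:01:02
Boende	bonobo	Papa-A	Papa-A*03:06
Boende	bonobo	Papa-B	Papa-B*15:01
Boende	bonobo	Papa-C	Papa-C*06:01:01:02
Bolobo	bonobo	Papa-A	Papa-A*05:03
Bolobo	bonobo	Papa-B	Papa-B*07:01:02
Bolobo	bonobo	Papa-C	Papa-C*03:02
Fizi	bonobo	Papa-A	Papa-A*03:02	Papa-A*08:03
Fizi	bonobo	Papa-B	Papa-B*09:01	Papa-B*19:02
Fizi	bonobo	Papa-C	Papa-C*04:02	Papa-C*03:02
Isiro	bonobo	Papa-A	Papa-A*05:03	Papa-A*06:03:01:01
Isiro	bonobo	Papa-B	Papa-B*02:02	Papa-B*07:01:02
Isiro	bonobo	Papa-C	Papa-C*03:01:01:03	Papa-C*03:02
Keza	bonobo	Papa-A	Papa-A*09:02	Papa-A*08:02
Keza	bonobo	Papa-B	Papa-B*01:03	Papa-B*17:01
Keza	bonobo	Papa-C	Papa-C*04:01	Papa-C*05:02
Kikwit	bonobo	Papa-A	Papa-A*06:03:01:02	Papa-A*05:03
Kikwit	bonobo	Papa-B	Papa-B*09:01	Papa-B*07:01:02
Kikwit	bonobo	Papa-C	Papa-C*04:02	Papa-C*03:02
Kisantu	bonobo	Papa-A	Papa-A*05:03	Papa-A*08:03
Kisantu	bonobo	Papa-B	Papa-B*07:01:02
Kisantu	bonobo	Papa-C	Papa-C*03:02
Kubulu	bonobo	Papa-A	Papa-A*03:06	Papa-A*06:03:01:03
Kubulu	bonobo	Papa-B	Papa-B*15:01	Papa-B*19:01
Kubulu	bonobo	Papa-C	Papa-C*06:01:01:02	Papa-C*05:01
Likasi	bonobo	Papa-A	Papa-A*06:03:01:01
Likasi	bonobo	Papa-B	Papa-B*02:02
Likasi	bonobo	Papa-C	Papa-C*03:01:01:03
Lipopo	bonobo	Papa-A	Papa-A*03:05
Lipopo	bonobo	Papa-B	Papa-B*19:02	Papa-B*16:01
Lipopo	bonobo	Papa-C	Papa-C*03:03:01:01	Papa-C*05:03
Lodja	bonobo	Papa-A	Papa-A*08:03	Papa-A*03:02
Lodja	bonobo	Papa-B	Papa-B*07:01:02	Papa-B*19:02
Lodja	bonobo	Papa-C	Papa-C*03:02	Papa-C*03:03:01:01
Lomami	bonobo	Papa-A	Papa-A*08:03	Papa-A*06:03:01:03
Lomami	bonobo	Papa-B	Papa-B*19:02	Papa-B*14:01
Lomami	bonobo	Papa-C	Papa-C*03:03:01:01	Papa-C*04:03
Malou_L	bonobo	Papa-A	Papa-A*08:03	Papa-A*04:02
Malou_L	bonobo	Papa-B	Papa-B*19:02	Papa-B*07:01:02
Malou_L	bonobo	Papa-C	Papa-C*03:02	Papa-C*03:03:01:01
Matadi	bonobo	Papa-A	Papa-A*08:03	Papa-A*06:03:01:02
Matadi	bonobo	Papa-B	Papa-B*15:02	Papa-B*07:01:02
Matadi	bonobo	Papa-C	Papa-C*03:02	Papa-C*06:01:01:02
Max	bonobo	Papa-A	Papa-A*05:03	Papa-A*06:03:01:01
Max	bonobo	Papa-B	Papa-B*02:02	Papa-B*15:01
Max	bonobo	Papa-C	Papa-C*03:01:01:03	Papa-C*06:01:01:02
Semwendwa	bonobo	Papa-A	Papa-A*06:02	Papa-A*04:02
Semwendwa	bonobo	Papa-B	Papa-B*01:02	Papa-B*08:01:01
Semwendwa	bonobo	Papa-C	Papa-C*04:02	Papa-C*03:03:01:02
Tshilomba	bonobo	Papa-A	Papa-A*03:02	Papa-A*03:06
Tshilomba	bonobo	Papa-B	Papa-B*14:01	Papa-B*07:01:02
Tshilomba	bonobo	Papa-C	Papa-C*03:02	Papa-C*04:03
Ulindi	bonobo	Papa-A	Papa-A*05:03	Papa-A*03:02
Ulindi	bonobo	Papa-B	Papa-B*07:01:02
Ulindi	bonobo	Papa-C	Papa-C*03:02
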