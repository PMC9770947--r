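gene	pathway	proteoform	in_sw480	in_sw620	intensity_sw480	intensity_sw620
MARK2	WNT/beta-catenin signaling	M.(S)[acetyl]SARTPLPTLNERDTEQPTLGHLDSK(PSSKSNMIRGRNSAT) (mass shift: 96 Da, phospho and oxidation)SADEQPHIGNY.R	yes	no	4.8e5	2.8e4
SOX9	WNT/beta-catenin signaling	R.SQYDYTDHQNSSSYYSHAAGQGTGLYSTFTYMNPAQRPMYTPIADTSGV(PSIPQTHS) (mass shift: 78 Da, phospho)PQHWEQPVYTQLTRP.	yes	no	3.0e5	4.6e4
EIF4B	mTOR signaling	M.AASAKKKNK(KGKTISLTDFL) (mass shift: 122 Da, phospho and acetylation/trimethylation)AEDGGTGGGSTYVSKPVSWADETDDLEGDVSTTWHSNDDDVYRAPPIDRSILPTAPR.A	no	yes	7.5e4	4.4e5
EIF4B	mTOR signaling	M.(A)[acetyl]ASAKKKNKKGKTISLTDFLAEDGG(T) (mass shift: 80 Da, phospho)GGGSTYVSKPVSWADETDDLEGDVSTTWHSNDDDVYRAPPIDR.S	no	yes	5.0e4	3.1e5
EIF4EBP1	PI3K/AKT signaling	.MSGGSS(C)[carbamidomethylation]SQTPSRAIPAT(RRVVLGDGVQLPPGDYSTT) (mass shift: 81 Da, phospho) PGGTLFSTTPGGTRIIYDRKFLME(C) (carbamidomethylation) RNSPVTKTPPRDLPTIPGVTSPSSDEPPMEASQSHLRNSPEDKRAGGEESQFEMDI	no	yes	6.0e4	3.5e6
EIF4EBP1	PI3K/AKT signaling	K.TPPRDLPTIPGVTS(PSSDEPPMEASQSHLRNS) (mass shift: 81 Da, phospho) PEDKRAGGEESQFEMDI	yes	no	1.5e5	5.0e4
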