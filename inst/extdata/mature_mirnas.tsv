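name	mfe	sequence	length	gc	hit	evalue
Nat-miR156a	-55.1	ugacagaagagagugagcaca	21	47.6	bna-miR156	0.001
Nat-miR156b	-76.5	ugacagaagagagugagcaca	21	47.6	bna-miR156	0.001
Nat-miR157	-43.9	uugacagaagauagagagcac	21	42.9	ath-miR157	0.001
Nat-miR159a	-62.3	uuuggauugaagggagcucua	21	42.9	ath-miR159	0.001
Nat-miR159b	-90.6	uuuggauugaagggagcucua	21	42.9	ath-miR159	0.001
Nat-miR159c	-104.3	uuuggauugaagggagcucua	21	42.9	ath-miR159	0.001
Nat-miR160a	-61.6	ugccuggcucccuguaugcca	21	61.9	ath-miR160	0.001
Nat-miR160b	-63.3	ugccuggcucccuguaugcca	21	61.9	ath-miR160	0.001
Nat-miR162	-43.9	uggaggcagcgguucaucgauc	22	54.5	csi-miR162	0.0001
Nat-miR164	-74.2	uggagaagcagggcacgugca	21	61.9	ath-miR164	0.001
Nat-miR166a	-59.8	ucggaccaggcuucauucccc	21	61.9	ath-miR166	0.001
Nat-miR166b	-51	ucggaccaggcuucauucccc	21	61.9	ath-miR166	0.001
Nat-miR166c	-71.8	ucggaccaggcuucauucccc	21	61.9	ath-miR166	0.001
Nat-miR167a	-42	ugaagcugccagcaugaucua	21	47.6	ath-miR167	0.001
Nat-miR167b	-47	ugaagcugccagcaugaucua	21	47.6	ath-miR167	0.001
Nat-miR168	-78.3	cccgccuugcaucaacugaau	21	52.4	aly-miR168	0.001
Nat-miR169a	-86.1	cagccaaggaugacuugccga	21	57.1	ath-miR169	0.001
Nat-miR169b	-70.5	uagccaaggaugacuugccugc	22	50.0	bna-miR169	0.001
Nat-miR171a	-70.1	ugauugagccgcgucaauauc	21	47.1	vvi-miR171	0.001
Nat-miR171b	-61.4	ugauugagccgcgucaauauc	21	47.1	vvi-miR171	0.001
Nat-miR171c	-44.9	ugauugagccgcgucaauauc	21	47.1	vvi-miR171	0.001
Nat-miR171d	-60.4	ugauugagccgcgucaauauc	21	47.1	vvi-miR171	0.001
Nat-miR172a	-53.4	ugagaaucuugaugaugcugcau	23	39.1	vvi-miR172	0.001
Nat-miR172b	-49.5	ugagaaucuugaugaugcugcau	23	39.1	vvi-miR172	0.001
Nat-miR172c	-61.7	ugagaaucuugaugaugcugcau	23	39.1	vvi-miR172	0.001
Nat-miR172d	-35.2	ugagaaucuugaugaugcugcau	23	39.1	vvi-miR172	0.001
Nat-miR319a	-97.5	uuggacugaagggagcucccu	21	57.1	ath-miR319	0.001
Nat-miR319b	-89.7	uuggacugaagggagcucccu	21	57.1	ath-miR319	0.001
Nat-miR319c	-95.4	uuggacugaagggagcucccu	21	57.1	ath-miR319	0.001
Nat-miR390a	-67.6	aagcucaggagggauagcacc	21	57.1	gma-miR390	0.001
Nat-miR390b	-58.1	aagcucaggagggauagcacc	21	57.1	gma-miR390	0.001
Nat-miR393a	-41.7	uccaaagggaucgcauugaucc	21	45.5	ath-miR393	0.0004
Nat-miR393b	-54.4	uccaaagggaucgcauugaucc	21	45.5	ath-miR393	0.0004
Nat-miR394a	-41.7	uuggcauucuguccaccuccau	22	50.0	vvi-miR394	0.0004
Nat-miR394b	-82.3	uuggcauucuguccaccuccau	22	50.0	vvi-miR394	0.0004
Nat-miR396	-56.4	uuccacagcuuucuugaacug	22	42.9	ath-miR396	0.001
Nat-miR397	-49.9	ucauugagugcagcguugaug	22	47.6	ath-miR397	0.001
Nat-miR398	-69.1	uguguucucaggucaccccuu	21	52.4	ath-miR398	0.001
Nat-miR399	-	ugccaaagaagauuugccccgu	21	52.4	ptc-miR399	0.001
Nat-miR403	-38.2	uuagauucacgcacaaacucg	21	42.9	ath-miR403	0.001
Nat-miR408	-47.6	augcacugccucuucccuggc	21	61.9	ath-miR408	0.001
Nat-miR413	-	cuaguuucucuuguucugcuu	21	38.1	ath-miR413	0.015
Nat-miR414	-	uccucuucaucaucaucuuc	21	40.0	ath-miR414	0.074
Nat-miR477	-54.8	acucucccucaagggcuucug	21	57.1	aqc-miR477	0.001
Nat-miR478	-33.3	ugacaugucuuauauuuuuag	20	23.8	ptc-miR478	0.005
Nat-miR482	-53.1	uuuccaauuccacccauuccua	21	40.9	sly-miR482	0.0004
Nat-miR828	-46.7	ucuugcucaaaugaguauucca	21	36.4	vvi-miR828	0.0004
Nat-miR845a	-	ugcucugauaccaaauugaug	22	38.1	ath-miR845	0.003
Nat-miR845b	-	uggcucugauaccaauugau	22	40.0	vvi-miR845	0.004
Nat-miR1128	-85.4	uacuacucccuccguuucaa	20	45.0	ssp-miR1128	0.081
Nat-miR1133	-88.1	cauauacucccuccgucccugaaa	21	50.0	tae-miR1133	0.017
Nat-miR1446	-48.7	uucugaacucucucccucaa	20	45.0	ptc-miR1446	0.003
Nat-miR1863a	-	gcucugauaccauguuaacu	24	40.0	osa-miR1863b	0.008
Nat-miR1863b	-	gacucugauaccauguuaaaauag	20	28.0	osa-miR1863	0.02
Nat-miR1919	-87.1	aggcgagtcatctgtgacagg	21	57.1	sly-miR1919	0.029
Nat-miR2911	-67.3	ggccgggggacggacuggga	20	80.0	peu-miR2911	0.014
Nat-miR5281a	-51.9	cauauaaauugaaacggagggag	23	39.1	mtr-miR5281b	0.13
Nat-miR5281b	-69.9	cauauaaauugaaacggagggag	23	39.1	mtr-miR5281b	0.13
Nat-miR5281c	-34.2	cauauaaauugaaacggagggag	23	39.1	mtr-miR5281b	0.13
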