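sample_id	condition	time	replicate
PBS_2h_r1	PBS	2h	1
PBS_2h_r2	PBS	2h	2
PBS_2h_r3	PBS	2h	3
MPL_2h_r1	MPL	2h	1
MPL_2h_r2	MPL	2h	2
MPL_2h_r3	MPL	2h	3
QS21_2h_r1	QS21	2h	1
QS21_2h_r2	QS21	2h	2
QS21_2h_r3	QS21	2h	3
AS01_2h_r1	AS01	2h	1
AS01_2h_r2	AS01	2h	2
AS01_2h_r3	AS01	2h	3
PBS_4h_r1	PBS	4h	1
PBS_4h_r2	PBS	4h	2
PBS_4h_r3	PBS	4h	3
MPL_4h_r1	MPL	4h	1
MPL_4h_r2	MPL	4h	2
MPL_4h_r3	MPL	4h	3
QS21_4h_r1	QS21	4h	1
QS21_4h_r2	QS21	4h	2
QS21_4h_r3	QS21	4h	3
AS01_4h_r1	AS01	4h	1
AS01_4h_r2	AS01	4h	2
AS01_4h_r3	AS01	4h	3
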