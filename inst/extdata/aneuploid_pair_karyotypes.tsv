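sample_id	treatment	egg_karyotype	pb_karyotype	reported_type
Sample 1	25nM	sseq cht(1)x4	sseq cht(1)x0	NDJ
Sample 2	50nM	sseq cht(4)x4	sseq cht(4)x0	NDJ
Sample 3	50nM	sseq cht(4)x4	sseq cht(4)x0	NDJ
Sample 4	50nM	sseq cht(7)x0	sseq cht(7)x4	NDJ
Sample 5	50nM	sseq cht(1)x1	sseq cht(1)x3	PSSC
Sample 6	50nM	sseq cht(8,11)x0	sseq cht(8,11)x4	NDJ
Sample 7	50nM	sseq cht(2,16,18)x4	sseq cht(2,16,18)x0	NDJ
Sample 8	50nM	sseq cht(14)x4, cht(18)x0	sseq cht(14)x0, cht(18)x4	NDJ
Sample 9	50nM	sseq cht(9)x0, cht(12,14)x4	sseq cht(9)x4, cht(12,14)x0	NDJ
Sample 10	50nM	sseq cht(4,9,16,19)x0	sseq cht(4,9,16,19)x4	NDJ
Sample 11	50nM	sseq cht(1,8)x0, cht(4,18)x4	sseq cht(1,8)x4, cht(4,18)x0	NDJ
Sample 12	50nM	sseq cht(5)x4, cht(6,12,14)x0	sseq cht(5)x0, cht(6,12,14)x4	NDJ
Sample 13	50nM	sseq cht(1,10,17)x0, cht(2)x3	sseq cht(1,10,17)x4, cht(2)x1	NDJ+PSSC
Sample 14	50nM	sseq cht(X, 1-6,8-19)x0, cht(7)x4	sseq cht(X , 1-6,8-19)x4, cht(7)x0	NDJ
Sample 15	50nM	sseq cht(X, 1-6,8-19)x0, cht(7)x4	sseq cht(X , 1-6,8-19)x4, cht(7)x0	NDJ
Sample 16	50nM	sseq cht(X, 1-10,12,13,15-19)x0, cht(11,14)x3	sseq cht(X , 1-10,12,13,15-19)x4, cht(11,14)x1	NDJ+PSSC
Sample 17	50nM	sseq cht(X, 1-4, 6-17,19)x0, cht(5,18)x3	sseq cht(X , 1-4, 6-17,19)x4, cht(5,18)x1	NDJ+PSSC
Sample 18	50nM	sseq cht(1,3-8,10-13,15-19)x0, cht(X, 2,9,14)x3	sseq cht(1,3-8,10-13,15-19)x4, cht(X , 2,9,14)x1	NDJ+PSSC
Sample 19	50nM	sseq cht(X, 1,3-9,12,13)x3, cht(2,10,11,14,16-19)x0, cht(15)x1	sseq cht(X , 1,3-9, 12,13)x1, cht(2,10,11,14,16-19)x4, cht(15)x3	NDJ+PSSC
Sample 20	50nM	sseq cht(X, 1-4,6-8,11-17,19)x0, cht(5)x4, cht(9,10,18)x3	sseq cht(X , 1-4,6-8,11-17,19)x4, cht(5)x0, cht(9,10,18)x1	NDJ+PSSC
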