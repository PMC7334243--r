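pair_id	arm	marker_type	start_frac	end_frac
1	short	CPD	0	0.31
2	short	CPD	0	0.31
4	short	CPD	0	0.31
5	short	CPD	0	0.31
6	short	CPD	0	0.31
7	short	CPD	0	0.31
8	short	CPD	0	0.31
9	short	CPD	0	0.31
10	short	CPD	0	0.31
11	short	CPD	0	0.31
1	long	CPD	0	0.31
2	long	CPD	0	0.31
3	long	CPD	0	0.31
4	long	CPD	0	0.31
5	long	CPD	0	0.31
6	long	CPD	0	0.31
7	long	CPD	0	0.31
8	long	CPD	0	0.31
9	long	CPD	0	0.31
10	long	CPD	0	0.31
11	long	CPD	0	0.31
3	short	CPD	0	1
3	short	45S	0	1
11	short	5S	0.1155	0.21550000000000002
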