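behaviour_id,barrier_id,influence_median,influence_iqr_low,influence_iqr_high,difficulty_median,difficulty_iqr_low,difficulty_iqr_high
1,1.1,6.0,5.0,6.0,2.0,1.0,2.0
1,1.2,5.0,4.0,5.0,3.0,2.0,4.0
1,1.3,3.0,3.0,4.0,3.0,3.0,4.0
1,1.4,3.0,2.0,4.0,4.0,3.0,5.0
1,1.5,2.0,1.0,4.0,5.0,2.0,6.0
1,1.6,2.0,1.0,2.0,5.0,4.0,6.0
2,2.1,7.5,5.5,9.0,3.0,2.0,4.5
2,2.2,7.5,5.0,9.0,4.5,2.5,7.5
2,2.3,7.0,4.0,9.0,2.5,1.0,6.5
2,2.4,6.0,4.0,8.0,4.0,2.0,6.0
2,2.5,5.5,4.5,8.0,7.0,5.0,8.5
2,2.6,5.5,2.0,8.0,5.5,3.0,7.5
2,2.7,5.0,3.0,7.0,6.5,2.0,7.0
2,2.8,4.0,3.0,5.5,5.0,4.0,8.5
2,2.9,3.0,1.0,5.0,6.5,5.0,8.0
3,3.1,6.5,3.5,7.0,2.5,2.0,5.0
3,3.2,6.5,2.0,8.0,4.0,1.0,7.0
3,3.3,5.5,2.5,6.5,3.0,2.0,5.0
3,3.4,5.0,3.5,6.5,3.0,1.0,5.0
3,3.5,4.5,3.5,6.0,4.5,3.0,5.0
3,3.6,4.0,1.5,5.0,6.0,4.0,8.0
3,3.7,3.0,2.0,5.0,6.5,5.0,8.0
3,3.8,2.5,1.5,5.0,6.5,5.0,7.0
4,4.1,4.0,3.5,5.0,3.5,2.5,5.0
4,4.2,4.0,3.0,5.0,1.0,1.0,2.5
4,4.3,2.5,1.5,4.0,2.0,2.0,4.5
4,4.4,2.0,1.5,3.0,3.0,2.0,4.0
4,4.5,2.0,1.0,4.0,4.0,3.0,5.0
5,5.1,3.0,2.5,4.0,3.5,1.5,4.0
5,5.2,2.5,1.0,3.5,3.0,1.5,4.0
5,5.3,2.0,1.0,3.0,1.5,1.0,2.0
5,5.4,2.0,2.0,3.5,2.5,2.0,3.0
6,6.1,2.0,1.0,2.0,2.0,1.0,2.0
6,6.2,1.0,1.0,2.0,1.0,1.0,2.0
7,7.1,5.5,4.0,7.0,3.0,1.0,4.0
7,7.2,5.5,4.0,7.0,3.0,1.0,3.5
7,7.3,5.0,2.0,6.0,6.0,4.5,6.5
7,7.4,3.5,1.5,6.0,3.5,2.0,4.5
7,7.5,3.5,3.0,6.0,3.5,2.0,5.0
7,7.6,2.5,1.0,4.5,5.0,4.5,6.5
7,7.7,2.0,2.0,4.0,5.5,3.0,7.0
8,8.1,8.0,6.0,8.0,2.0,1.0,2.0
8,8.2,5.0,4.0,7.0,2.0,2.0,3.0
8,8.3,5.0,2.0,6.0,4.0,3.0,6.0
8,8.4,5.0,4.0,6.0,5.0,5.0,7.0
8,8.5,5.0,3.0,7.0,4.0,2.0,5.0
8,8.6,4.0,3.0,6.0,5.0,3.0,6.0
8,8.7,3.0,1.0,4.0,7.0,4.0,8.0
8,8.8,4.0,2.0,4.0,7.0,6.0,8.0
9,9.1,4.0,4.0,4.0,1.0,1.0,1.5
9,9.2,3.0,2.0,3.0,2.0,1.5,2.0
9,9.3,2.0,1.5,2.5,3.0,2.5,3.5
9,9.4,1.5,1.0,2.0,4.0,3.0,4.0
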