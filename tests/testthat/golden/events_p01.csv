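# socialgaze config_md5=8ef22bf32e94caa5c22a038259694af5 seed=20260101
t,actor,kind,target,macro_state,block,participant
0,agent,gaze_shift,STRAIGHT,IJA,1,p01
0,human,dwell_onset,A,RJA,1,p01
2036,agent,gaze_shift,O1,IJA,1,p01
2324,human,dwell_offset,A,RJA,1,p01
2354,human,dwell_onset,O1,RJA,1,p01
3320,agent,gaze_shift,STRAIGHT,IJA,1,p01
3466,human,dwell_offset,O1,RJA,1,p01
3496,human,dwell_onset,A,RJA,1,p01
4351,agent,gaze_shift,O3,IJA,1,p01
4838,human,dwell_offset,A,RJA,1,p01
4868,human,dwell_onset,O3,RJA,1,p01
5569,agent,gaze_shift,STRAIGHT,IJA,1,p01
5852,human,dwell_offset,O3,RJA,1,p01
5882,human,dwell_onset,A,RJA,1,p01
6739,agent,gaze_shift,O1,IJA,1,p01
7255,human,dwell_offset,A,RJA,1,p01
7285,human,dwell_onset,O1,RJA,1,p01
8000,human,dwell_offset,O1,RJA,1,p01
0,agent,gaze_shift,O2,OO,2,p01
0,human,dwell_onset,A,OO,2,p01
420,human,dwell_offset,A,OO,2,p01
450,human,dwell_onset,O2,OO,2,p01
1022,agent,gaze_shift,O3,OO,2,p01
2289,human,dwell_offset,O2,OO,2,p01
2319,human,dwell_onset,O3,OO,2,p01
3031,agent,gaze_shift,O4,OO,2,p01
3165,human,dwell_offset,O3,OO,2,p01
3195,human,dwell_onset,O4,OO,2,p01
3917,agent,gaze_shift,STRAIGHT,OO,2,p01
4055,human,dwell_offset,O4,OO,2,p01
4085,human,dwell_onset,O3,OO,2,p01
5539,human,dwell_offset,O3,OO,2,p01
5569,human,dwell_onset,A,OO,2,p01
6585,human,dwell_offset,A,OO,2,p01
6601,agent,gaze_shift,O2,OO,2,p01
6615,human,dwell_onset,O1,OO,2,p01
7880,human,dwell_offset,O1,OO,2,p01
7910,human,dwell_onset,O2,OO,2,p01
8000,human,dwell_offset,O2,OO,2,p01
0,agent,gaze_shift,O4,PO,3,p01
0,human,dwell_onset,O1,PO,3,p01
409,human,dwell_offset,O1,PO,3,p01
439,human,dwell_onset,A,PO,3,p01
607,agent,gaze_shift,STRAIGHT,PO,3,p01
1533,agent,gaze_shift,O3,PO,3,p01
1617,human,dwell_offset,A,PO,3,p01
1647,human,dwell_onset,O4,PO,3,p01
1952,human,dwell_offset,O4,PO,3,p01
1982,human,dwell_onset,A,PO,3,p01
2022,agent,gaze_shift,STRAIGHT,PO,3,p01
3984,agent,gaze_shift,O4,PO,3,p01
4858,agent,gaze_shift,STRAIGHT,PO,3,p01
5484,human,dwell_offset,A,PO,3,p01
5514,human,dwell_onset,O4,PO,3,p01
5729,human,dwell_offset,O4,PO,3,p01
5759,human,dwell_onset,A,PO,3,p01
7135,human,dwell_offset,A,PO,3,p01
7165,human,dwell_onset,O1,PO,3,p01
7426,human,dwell_offset,O1,PO,3,p01
7456,human,dwell_onset,A,PO,3,p01
7887,agent,gaze_shift,O1,PO,3,p01
8000,human,dwell_offset,A,PO,3,p01
0,agent,gaze_shift,STRAIGHT,INT,4,p01
0,human,dwell_onset,O4,INT,4,p01
509,human,dwell_offset,O4,INT,4,p01
539,human,dwell_onset,DOWN,INT,4,p01
674,agent,gaze_shift,DOWN,INT,4,p01
5626,agent,gaze_shift,O4,INT,4,p01
6175,agent,gaze_shift,DOWN,INT,4,p01
8000,human,dwell_offset,DOWN,INT,4,p01
0,agent,gaze_shift,STRAIGHT,RJA,5,p01
0,human,dwell_onset,A,IJA,5,p01
877,human,dwell_offset,A,IJA,5,p01
907,human,dwell_onset,O4,IJA,5,p01
1276,agent,gaze_shift,O4,RJA,5,p01
1721,human,dwell_offset,O4,IJA,5,p01
1751,human,dwell_onset,A,IJA,5,p01
2424,agent,gaze_shift,STRAIGHT,RJA,5,p01
2650,human,dwell_offset,A,IJA,5,p01
2680,human,dwell_onset,O4,IJA,5,p01
3156,agent,gaze_shift,O4,RJA,5,p01
3502,human,dwell_offset,O4,IJA,5,p01
3532,human,dwell_onset,O3,IJA,5,p01
3951,agent,gaze_shift,STRAIGHT,RJA,5,p01
4404,human,dwell_offset,O3,IJA,5,p01
4434,human,dwell_onset,A,IJA,5,p01
5294,human,dwell_offset,A,IJA,5,p01
5324,human,dwell_onset,O1,IJA,5,p01
5788,agent,gaze_shift,O1,RJA,5,p01
6315,human,dwell_offset,O1,IJA,5,p01
6345,human,dwell_onset,A,IJA,5,p01
6705,agent,gaze_shift,STRAIGHT,RJA,5,p01
7200,human,dwell_offset,A,IJA,5,p01
7230,human,dwell_onset,O1,IJA,5,p01
7775,agent,gaze_shift,O1,RJA,5,p01
8000,human,dwell_offset,O1,IJA,5,p01
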