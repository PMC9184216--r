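time,status,stage
0.6,1,1
1.3,1,1
2.4,1,1
2.5,0,1
3.2,1,1
3.3,0,1
3.5,1,1
3.5,1,1
4.0,1,1
4.0,1,1
4.3,1,1
4.5,0,1
4.5,0,1
5.3,1,1
5.5,0,1
5.9,0,1
5.9,0,1
6.0,1,1
6.1,0,1
6.2,0,1
6.4,1,1
6.5,1,1
6.5,0,1
6.7,0,1
7.0,0,1
7.4,1,1
7.4,0,1
8.1,0,1
8.1,0,1
9.6,0,1
10.7,0,1
0.2,1,2
1.8,1,2
2.0,1,2
2.2,0,2
2.6,0,2
3.3,0,2
3.6,1,2
4.0,0,2
4.3,1,2
4.3,0,2
5.0,0,2
6.2,1,2
7.0,1,2
7.5,0,2
7.6,0,2
9.3,0,2
0.3,1,3
0.3,1,3
0.5,1,3
0.7,1,3
0.8,1,3
1.0,1,3
1.3,1,3
1.6,1,3
1.8,1,3
1.9,1,3
1.9,1,3
3.2,1,3
3.5,1,3
3.7,0,3
4.5,0,3
4.8,0,3
4.8,0,3
5.0,1,3
5.0,0,3
5.1,0,3
6.3,1,3
6.4,1,3
6.5,0,3
7.8,1,3
8.0,0,3
9.3,0,3
10.1,0,3
0.1,1,4
0.3,1,4
0.4,1,4
0.8,1,4
0.8,1,4
1.0,1,4
1.5,1,4
2.0,1,4
2.3,1,4
2.9,0,4
3.6,1,4
3.8,1,4
4.3,0,4
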