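patient,trials,tp,fp,fn,tn
1,42,7,0,0,49
2,36,3,2,0,41
3,38,7,2,0,47
4,42,4,3,0,49
5,39,5,3,0,47
6,18,7,1,3,26
7,19,3,3,0,14
8,20,5,0,0,15
9,19,4,0,0,23
10,25,6,0,1,31
11,35,3,2,0,40
12,24,31,6,9,61
13,33,8,8,4,48
14,26,7,2,1,35
15,36,18,6,1,64
16,20,8,1,2,28
17,23,3,0,0,24
18,36,5,2,1,44
19,30,3,0,0,33
20,28,8,0,0,38
21,33,4,1,0,38
22,30,3,0,0,33
23,9,6,0,1,16
24,22,16,4,0,42
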