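patient,trials,tp,fp,fn,tn
1,42,6,3,1,48
2,36,2,3,1,38
3,38,7,0,0,45
4,42,2,2,1,44
5,39,5,1,0,44
7,19,3,1,0,21
8,20,5,0,0,25
9,19,3,0,0,22
10,25,6,1,1,31
11,35,2,3,1,37
17,23,3,0,0,26
18,36,5,1,1,41
19,30,3,0,0,33
20,28,5,2,1,33
22,30,3,1,0,33
23,9,2,0,1,11
24,22,15,2,1,36
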