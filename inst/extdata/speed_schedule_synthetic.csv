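level,speed_cm_s
1,17
2,25
3,33
4,41
5,49
6,57
7,65
8,73
9,81
10,89
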