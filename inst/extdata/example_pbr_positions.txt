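5
7
9
19
24
45
59
61
62
63
66
67
70
74
77
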