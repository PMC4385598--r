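L,a,b,A1,A4,B4,C4,D4
66.89667,-0.01,14.92667,0.32,0,0,0.08,0
72.46333,-1.33333,14.58667,0.32,0,0,0,0.08
65.74667,1.33,19.24333,0.16,0,0.16,0.08,0
69.91667,1.136667,18.86667,0.16,0,0.08,0.08,0.08
65.10667,1.513333,19.40333,0.16,0.08,0,0.08,0.08
67.76333,0.643333,20.15667,0.16,0.08,0.08,0,0.08
65.49667,1.73,20.37333,0.16,0.08,0.08,0.08,0
63.86667,1.81,20.13,0.08,0,0.16,0.16,0
65.42,1.366667,21.55,0.08,0,0.16,0.08,0.08
64.71667,1.663333,18.87333,0.08,0,0.08,0.16,0.08
65.76667,1.56,20.55333,0.08,0,0.08,0.08,0.16
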