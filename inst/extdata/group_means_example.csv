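value,weight
0.7755,4
0.6229,3
1.8207,5
2.2878,3
1.7054,4
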