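length	offset
20	12
21	12
22	12
23	12
24	12
25	12
26	12
27	12
28	12
29	12
30	12
31	12
32	12
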