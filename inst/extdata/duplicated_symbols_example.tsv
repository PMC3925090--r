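gene	s1	s2	s3
TNF	10	20	30
tnf	14	22	34
IL6	5	6	7
Tnf	12	24	38
COL2A1	8	9	10
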