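# Measured and matrix-predicted LacI binding energies (kBT) for operator
# mutants of the O1 lac operator. Predictions come from an O1-reference
# energy matrix (R = 130 background); measured values are titration fits.
sequence	predicted	measured
AATTGTGAGCGGAGAACAATT	-12.63	-12.24
AATTGTGAGCGCATAACAATT	-15.71	-15.30
AATTGTGAGCGGATCACAATT	-15.22	-14.99
AATTGTGAGCGGAAAACAATT	-12.91	-12.50
AATTGCGAGCGGATAACAATT	-12.14	-11.30
AATTGTGAGGGGATAACAATT	-13.16	-12.35
AATTGTGAGCGGATATCAATT	-13.66	-13.29
AATTGTGAGCAGATAACAATT	-11.11	-10.25
AATTGTGAGAGGATAACAATT	-8.89	-10.00
AATTGTGAGCGGGTAACAACT	-13.82	-14.79
AAATGTGAGCGGATAACAACT	-13.61	-14.40
AATTGTGAGCGAGTAACAATT	-14.36	-15.12
ATTTGTGAGCGGAGAACAATT	-12.55	-11.52
CATTGTGAGCGCATAACAATT	-15.34	-14.80
AATTGTGAGCGGAACACAATT	-12.83	-13.31
AATTGTGAGCGGAATACAATT	-11.70	-12.03
AATTGCGAGCGGATAACAAAT	-12.06	-10.78
AATTGTGAGGGGATAACAATC	-14.13	-12.15
AAATGTGAGCGAGTAACAATT	-13.84	-14.57
AATTGTGAGCGAGTAACAACT	-13.19	-14.67
ATTTGTGAGCGAAGAACAATT	-11.92	-10.83
CATTGTGAGCGCATAACATTT	-15.39	-14.18
AATTGTGAGCGGAACACAATG	-13.72	-12.17
AATTGTGAGCGGGATACAATT	-11.39	-11.86
AATTGCGAGCGGATAACAAAG	-12.96	-10.62
AATTGTGAGGGTATAACAATC	-14.10	-11.79
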