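morphology,count
N,75052
L,8075
R,7259
V,7130
P,7028
A,2546
ALL,109494
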