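route,sz
A,89.34
B,86.08
C,100.17
Actual,111.43
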