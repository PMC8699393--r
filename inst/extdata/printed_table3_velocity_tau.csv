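experiment,tau_fa,tau_fmc
a,0.10,0.18
b,0.02,-0.02
c,0.25,0.19
d,0.06,0.04
e,0.08,0.06
f,0.19,0.15
g,0.11,0.02
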