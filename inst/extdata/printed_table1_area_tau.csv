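experiment,tau_fa,tau_fmc
a,0.55,0.53
b,0.15,0.11
c,0.76,0.68
d,0.51,0.45
e,0.13,0.08
f,0.55,0.51
g,0.54,0.41
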