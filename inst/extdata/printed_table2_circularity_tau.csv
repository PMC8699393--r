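experiment,tau_fa,tau_fmc
a,-0.19,-0.22
b,-0.02,-0.05
c,-0.35,-0.36
d,-0.24,-0.23
e,0.10,0.16
f,-0.12,-0.16
g,-0.22,-0.18
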