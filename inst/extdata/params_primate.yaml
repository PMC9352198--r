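# Circuit constants, primate recordings
omega_d: 100
omega: 30
C: 15
mu: 6
alpha: 0.7
d0: 5
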