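# Circuit constants, mouse recordings
omega_d: 50
omega: 15
C: 15
mu: 6
alpha: 0.7
d0: 5
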