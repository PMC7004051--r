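pattern,qol_0,qol_6,qol_12,cost_total,usual care,CBT
oooo,obs,obs,obs,obs,182,186
ooom,obs,obs,obs,mis,13,6
omoo,obs,mis,obs,obs,0,2
oomm,obs,obs,mis,mis,18,14
omom,obs,mis,obs,mis,3,3
ommm,obs,mis,mis,mis,19,23
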