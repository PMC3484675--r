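# molecular-clock rates (substitutions per site per year)
rate.point = 1.25e-9
rate.low = 0.5e-9
rate.high = 1.35e-9

# presence/absence with divergence intervals (years) from the focal lineage
presence.neanderthal = present 2.7e5 8.0e5
presence.chimpanzee = absent 5.5e6 7e6

seed = 1
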