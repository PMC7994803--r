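# Serial endosymbiosis scenario, Bodyl-type transfer order.
# Rho = Rhodophytina (red algal donor), Cry = Cryptophyta,
# Och = Ochrophyta, Hap = Haptophyta, Myz = Myzozoa.
Rho -> Cry, level 2
Cry -> Och, level 3
Cry -> Hap, level 3
Hap -> Myz, level 4
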