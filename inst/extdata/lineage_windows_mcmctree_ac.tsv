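# Lineage availability windows (95% HPD bounds, Ma) under the MCMCTree
# autocorrelated-clock dating analysis. Older bound: older 95% HPD limit of
# the node opening the stem; younger bound: younger 95% HPD limit of the
# crown node.
# Rho = stem Rhodophytina (plastid donor lineage)
lineage	older	younger
Rho	1675	1281
Cry	1658	440
Och	1298	622
Hap	1943	579
Myz	1520	696
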