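table,outcome,era,arm,n_severe,denom
main,anxiety,preuniversal,not_vaccinated,1171,4846
main,anxiety,preuniversal,vaccinated,532,3194
main,depression,preuniversal,not_vaccinated,1231,4846
main,depression,preuniversal,vaccinated,653,3194
main,anxiety,universal,not_vaccinated,706,2628
main,anxiety,universal,vaccinated,219,801
main,depression,universal,not_vaccinated,782,2628
main,depression,universal,vaccinated,234,801
subgroup,anxiety,preuniversal,not_vaccinated,840,1292
subgroup,anxiety,preuniversal,vaccinated,361,656
subgroup,depression,preuniversal,not_vaccinated,895,1325
subgroup,depression,preuniversal,vaccinated,461,730
subgroup,anxiety,universal,not_vaccinated,494,739
subgroup,anxiety,universal,vaccinated,142,208
subgroup,depression,universal,not_vaccinated,549,789
subgroup,depression,universal,vaccinated,153,222
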