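# Approximate cytoplasmic Ca2+ uptake in immature rat hippocampal cells,
# repeated exposure: 100 mT static magnetic field for 15 min per day over
# 8 days (Hirai and co-workers). Percentages are relative to the maximal
# reading after 10 uM Ca2+ ionophore (A23187); values digitised from the
# published plots, so they carry ~1-d.p. precision. ratio_printed is the
# field/control ratio as printed alongside the source data.
nmda_um,control_pct,field_pct,ratio_printed
1,3.9,6.2,1.6
3,10.2,16.3,1.6
10,17.9,25.8,1.4
30,22.8,28.2,1.2
100,25.1,28.4,1.1
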