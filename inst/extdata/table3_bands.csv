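wavenumber,assignment
1720,C=O ester
1650,"Amide I, beta-sheet"
1604,C-C aromatic
1551,C-C aromatic
1520,"Amide II, C=N stretching"
1410,CH2 bending of lipids and fatty acids
1350,CH3 bending proteins and lipids and CH2 wagging and twisting
1240,OH bending
1196,C-O-C ester stretching
1145,C-O-C ester stretching
1055,C-O-C glycosidic bond
955,CH (trans OOP)
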