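variety,stage,reference,reference_sd,predicted_tga_mlr,predicted_ftir_pls
H1015,green,1176,54,851,1177
H1015,turning,519,29,481,482
H1015,pink,213,20,296,213
H1301,green,1829,41,1422,1820
H1301,turning,457,17,470,458
H1301,pink,161,12,229,160
H3402,green,796,41,830,797
H3402,turning,621,20,813,621
H3402,pink,141,11,189,144
H3406,green,1993,33,1735,1874
H3406,turning,449,18,544,454
H3406,pink,181,12,207,182
H5108,green,663,46,550,664
H5108,turning,489,28,486,461
H5108,pink,279,18,278,280
H7204,green,1231,36,1893,1182
H7204,turning,388,17,302,371
H7204,pink,176,17,133,177
Lyco1,green,768,63,811,742
Lyco1,turning,320,22,248,325
Lyco1,pink,242,32,247,239
Fokker,green,1080,102,766,1039
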