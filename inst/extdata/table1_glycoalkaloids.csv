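variety,stage,alpha_tomatine,alpha_tomatine_sd,dehydrotomatine,dehydrotomatine_sd,tomatine,tomatine_sd
H1015,green,1028,53,147,9,1176,54
H1015,turning,441,28,78,8,519,29
H1015,pink,180,19,34,5,213,20
H1301,green,1614,40,215,4,1829,41
H1301,turning,400,17,57,3,457,17
H1301,pink,141,12,21,2,161,12
H3402,green,688,40,109,11,796,41
H3402,turning,535,19,86,7,621,20
H3402,pink,120,11,21,3,141,11
H3406,green,1772,33,221,3,1993,33
H3406,turning,388,18,61,4,449,18
H3406,pink,155,11,26,3,181,12
H5108,green,552,45,111,7,663,46
H5108,turning,420,27,69,7,489,28
H5108,pink,238,17,42,6,279,18
H7204,green,1088,34,143,12,1231,36
H7204,turning,314,16,75,6,388,17
H7204,pink,148,17,28,4,176,17
H7204,red,14,2,NA,NA,14,2
Lyco1,green,678,62,90,8,768,63
Lyco1,turning,294,22,26,3,320,22
Lyco1,pink,217,32,25,4,242,32
Fokker,green,952,101,128,15,1080,102
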