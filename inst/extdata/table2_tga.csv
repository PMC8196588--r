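variety,stage,wl_120_200,wl_120_200_sd,wl_200_400,wl_200_400_sd
H1015,green,17.5,0.2,38.2,0.3
H1015,turning,19.0,0.2,36.4,0.2
H1015,pink,19.3,0.2,34.4,0.5
H1301,green,15.9,0.1,39.7,0.8
H1301,turning,19.0,0.4,36.3,0.3
H1301,pink,20.4,0.3,33.8,0.2
H3402,green,16.9,0.3,37.8,0.4
H3402,turning,17.5,0.5,38,0.1
H3402,pink,20.5,0.1,33,0.3
H3406,green,14.9,0.1,40.1,0.2
H3406,turning,18.5,0.6,36.7,0.3
H3406,pink,20.3,0.2,33.3,0.5
H5108,green,18.4,0.3,36.7,0.6
H5108,turning,18.7,0.2,36.3,0.5
H5108,pink,20.3,0.4,34.6,0.2
H7204,green,14.1,0.2,40.1,0.3
H7204,turning,18.9,0.3,34.3,0.4
H7204,pink,24.2,0.3,33.2,0.6
Lyco1,green,16.9,0.5,37.7,0.4
Lyco1,turning,19.9,0.4,33.9,0.6
Lyco1,pink,19.5,0.2,33.7,0.4
Fokker,green,16.8,0.2,37.4,0.5
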