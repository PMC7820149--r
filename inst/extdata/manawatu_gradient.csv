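site,DIN,DRP,richness,connectance,TST
Mangatainoka River @ Putara Road,0.02,0.003,33,0.11,8749303
Pohangina River @ Piripiri Road,0.05,0.005,62,0.09,16377036
Pohangina River @ Raumai Reserve,0.08,0.012,53,0.12,6629034
Tokomaru River @ Horseshoe Bend Reserve,0.08,0.005,67,0.12,19844310
Raparapawai Stream @ Jacksons Road,0.15,0.030,62,0.11,20767724
Oroua River @ Nelson Street,0.24,0.010,38,0.12,11872967
Manawatu River @ SH2,0.40,0.009,64,0.12,34246823
Mangatera Stream @ SH2,0.44,0.141,62,0.10,54782015
Oroua River @ Awahuri Road,0.53,0.101,37,0.09,34819550
Mangatera Stream @ Timber Bay,0.81,0.141,66,0.11,40277332
Manawatu River @ Hopelands Road,0.90,0.024,64,0.11,22250529
Mangapapa Stream @ Troup Road,0.90,0.024,67,0.12,40237153
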