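food,volume_cm3,toughness_Jm2,elastic_modulus_MPa
sunflower_seed,0.10,116.12,4.26
popcorn,0.17,2978.82,325.4
peanut,0.43,255.5,23.9
almond,1.29,308.62,19.42
gummy_bear,1.79,887.96,0.07
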