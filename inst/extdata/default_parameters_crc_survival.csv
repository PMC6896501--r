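"stage","year","annual_death_prob"
1,1,0.03
1,2,0.026
1,3,0.023
1,4,0.02
1,5,0.018
1,6,0.008
2,1,0.07
2,2,0.06
2,3,0.055
2,4,0.05
2,5,0.045
2,6,0.015
3,1,0.17
3,2,0.15
3,3,0.13
3,4,0.11
3,5,0.09
3,6,0.025
4,1,0.55
4,2,0.45
4,3,0.35
4,4,0.28
4,5,0.22
4,6,0.06
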