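group,case_id,major_axis_mm,volume_mm3
not_stone_free,nsf_1,2.387,8.34
not_stone_free,nsf_2,2.535,10.61
not_stone_free,nsf_3,3.516,10.78
not_stone_free,nsf_4,4.238,16.18
not_stone_free,nsf_5,4.386,19.11
stone_free_with_cirfs,cirf_1,1.642,2.38
stone_free_with_cirfs,cirf_2,2.304,7.05
stone_free_with_cirfs,cirf_3,3.516,10.30
stone_free_with_cirfs,cirf_4,3.672,11.73
stone_free_with_cirfs,cirf_5,3.854,26.07
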