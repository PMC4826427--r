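quantity,value
total_cancers,9149
cancers_with_known_dx,7792
allcancer_hr_men,1.01
allcancer_hr_women,1.07
prostate_hr_men,0.56
first_year_hr_men,2.28
first_year_hr_women,2.34
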