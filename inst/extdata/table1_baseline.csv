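characteristic,value
total,20
gender_male,16
gender_female,4
age_median_years,51
age_min_years,41
age_max_years,66
stage_III,17
stage_IVa,3
concurrent_chemotherapy_yes,20
concurrent_chemotherapy_no,0
radiotherapy_technique,IMRT
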