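characteristic	count	total
female_all	31	40
male_all	9	40
nonsmoker_all	30	40
smoker_all	10	40
female_tumor_retained	28	34
male_tumor_retained	6	34
nonsmoker_tumor_retained	27	34
smoker_tumor_retained	7	34
female_nc_retained	14	17
male_nc_retained	3	17
nonsmoker_nc_retained	14	17
smoker_nc_retained	3	17
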