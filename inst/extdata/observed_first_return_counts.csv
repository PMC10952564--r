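sex,category,count
female,dropout,98
female,returned,902
female,other_deferrals,49
female,donations_over,658
female,donations_under,125
female,low_hb_deferrals,69
male,dropout,66
male,returned,934
male,other_deferrals,37
male,donations_over,801
male,donations_under,68
male,low_hb_deferrals,27
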