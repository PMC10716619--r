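pollutant,days_below_guideline
pm25,227
pm10,1020
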