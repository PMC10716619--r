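city_id,children_monitored,days_monitored
Blantyre,24,81
Durban,47,180
Harare,43,162
Kumasi,61,237
Lagos,61,221
Moshi,61,228
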