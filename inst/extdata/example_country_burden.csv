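region,cause,age_group,mortality,dalys,o3_mortality
Cambodia,pm25_total,all,1500,59500,140
Laos,pm25_total,all,1600,63600,80
Myanmar,pm25_total,all,10800,393100,1070
Thailand,pm25_total,all,8500,344500,600
Vietnam,pm25_total,all,5100,186800,360
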