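# Modified Early Warning Score (MEWS), transcribed from Subbe et al. 2001,
# QJM 94:521-526. Bands are closed intervals on the chart's measurement
# precision (integer vitals, 0.1 degC temperature) and extended at the
# extremes to cover the full plausibility range.
component,lower,upper,code,points
systolic_bp,30,70,,3
systolic_bp,71,80,,2
systolic_bp,81,100,,1
systolic_bp,101,199,,0
systolic_bp,200,300,,2
heart_rate,10,40,,2
heart_rate,41,50,,1
heart_rate,51,100,,0
heart_rate,101,110,,1
heart_rate,111,129,,2
heart_rate,130,300,,3
resp_rate,0,8,,2
resp_rate,9,14,,0
resp_rate,15,20,,1
resp_rate,21,29,,2
resp_rate,30,80,,3
temperature,30,34.9,,2
temperature,35,38.4,,0
temperature,38.5,43,,2
avpu,,,A,0
avpu,,,V,1
avpu,,,P,2
avpu,,,U,3
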