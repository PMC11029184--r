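# National Early Warning Score (NEWS), transcribed from the Royal College of
# Physicians 2012 report "National Early Warning Score (NEWS): Standardising
# the assessment of acute-illness severity in the NHS". Bands are closed
# intervals on the chart's measurement precision, extended at the extremes
# to cover the plausibility range.
component,lower,upper,code,points
resp_rate,0,8,,3
resp_rate,9,11,,1
resp_rate,12,20,,0
resp_rate,21,24,,2
resp_rate,25,80,,3
spo2,50,91,,3
spo2,92,93,,2
spo2,94,95,,1
spo2,96,100,,0
supplemental_o2,,,TRUE,2
supplemental_o2,,,FALSE,0
temperature,30,35,,3
temperature,35.1,36,,1
temperature,36.1,38,,0
temperature,38.1,39,,1
temperature,39.1,43,,2
systolic_bp,30,90,,3
systolic_bp,91,100,,2
systolic_bp,101,110,,1
systolic_bp,111,219,,0
systolic_bp,220,300,,3
heart_rate,10,40,,3
heart_rate,41,50,,1
heart_rate,51,90,,0
heart_rate,91,110,,1
heart_rate,111,130,,2
heart_rate,131,300,,3
avpu,,,A,0
avpu,,,V,3
avpu,,,P,3
avpu,,,U,3
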