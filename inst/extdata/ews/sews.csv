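# Standardised Early Warning Score (SEWS), transcribed from Paterson et al.
# 2006, Clin Med 6:281-284. Bands are closed intervals on the chart's
# measurement precision, extended at the extremes to cover the plausibility
# range.
component,lower,upper,code,points
resp_rate,0,8,,2
resp_rate,9,20,,0
resp_rate,21,30,,1
resp_rate,31,35,,2
resp_rate,36,80,,3
spo2,50,84,,3
spo2,85,89,,2
spo2,90,92,,1
spo2,93,100,,0
temperature,30,33.9,,3
temperature,34,34.9,,2
temperature,35,35.9,,1
temperature,36,37.9,,0
temperature,38,38.9,,1
temperature,39,43,,2
systolic_bp,30,69,,3
systolic_bp,70,79,,2
systolic_bp,80,99,,1
systolic_bp,100,199,,0
systolic_bp,200,300,,3
heart_rate,10,29,,3
heart_rate,30,39,,2
heart_rate,40,49,,1
heart_rate,50,99,,0
heart_rate,100,109,,1
heart_rate,110,129,,2
heart_rate,130,300,,3
avpu,,,A,0
avpu,,,V,1
avpu,,,P,2
avpu,,,U,3
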