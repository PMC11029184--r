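# Centile-based Early Warning Score (CEWS), following the scheme of
# Tarassenko et al. 2011, Resuscitation 82:1013-1018: band boundaries at the
# 1st/5th/10th and 90th/95th/99th centiles of the vital-sign distributions
# of an acutely ill in-hospital population (3 points outside the 1st/99th,
# 2 points between 1st-5th / 95th-99th, 1 point between 5th-10th /
# 90th-95th, 0 inside 10th-90th; SpO2 penalised on the low side only).
# Boundaries are rounded to chart precision; the file is user-replaceable.
component,lower,upper,code,points
heart_rate,10,44,,3
heart_rate,45,50,,2
heart_rate,51,54,,1
heart_rate,55,103,,0
heart_rate,104,110,,1
heart_rate,111,127,,2
heart_rate,128,300,,3
systolic_bp,30,84,,3
systolic_bp,85,96,,2
systolic_bp,97,101,,1
systolic_bp,102,160,,0
systolic_bp,161,171,,1
systolic_bp,172,194,,2
systolic_bp,195,300,,3
resp_rate,0,8,,3
resp_rate,9,10,,2
resp_rate,11,12,,1
resp_rate,13,22,,0
resp_rate,23,25,,1
resp_rate,26,31,,2
resp_rate,32,80,,3
spo2,50,84,,3
spo2,85,89,,2
spo2,90,92,,1
spo2,93,100,,0
temperature,30,35.5,,3
temperature,35.6,35.9,,2
temperature,36,36.2,,1
temperature,36.3,37.3,,0
temperature,37.4,37.6,,1
temperature,37.7,38,,2
temperature,38.1,43,,3
avpu,,,A,0
avpu,,,V,1
avpu,,,P,2
avpu,,,U,3
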