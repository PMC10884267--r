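condition,prev,ci_low,ci_high,source
Arthritis,11.3,8.9,13.7,WHS 2003
Asthma,3.5,3.1,4.0,DHS 2016
COPD,1.8,1.5,2.2,DHS 2016
Depression,4.9,3.9,5.9,SASH 2002-4
Diabetes,10.2,8.9,11.7,SANHANES 2012
HIV/AIDS,18.2,17.5,18.6,Thembisa 2021
Hypertension,33.9,31.8,36.1,SANHANES 2012
IHD,5.6,4.5,6.9,SANHANES 2012
Stroke,2.6,2.0,3.5,SANHANES 2012
Tuberculosis,0.99,0.95,1.04,Thembisa 2021
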