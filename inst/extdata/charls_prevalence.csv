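name,n_patients,percent_reported
Dyslipidemia,1235,37.05
Hypertension,1193,35.79
Stomach or other digestive disease,892,26.76
Heart disease,864,25.92
Arthritis or rheumatism,799,23.97
Diabetes or high blood sugar,681,20.43
Chronic lung disease,639,19.17
Stroke,611,18.33
Kidney disease,489,14.67
Liver disease,417,12.51
Memory-related disease,325,9.75
Asthma,317,9.51
Emotional or psychiatric problem,168,5.04
Cancer or malignant tumor,147,4.41
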