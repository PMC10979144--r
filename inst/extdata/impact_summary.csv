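city,endpoint,ap_percent,excess_cases,per_100k
Arak,natural,7.39,353,71.43
Arak,lc,8.39,4,1.31
Arak,copd,10.43,6,1.95
Arak,alri,12.21,1,1.62
Arak,ihd,14.6,78,22.98
Arak,stroke,14.6,42,12.48
Esfahan,natural,8.61,389,66.88
Esfahan,lc,10.16,13,0.98
Esfahan,copd,12.37,20,1.56
Esfahan,alri,14.63,5,3.49
Esfahan,ihd,15.26,278,19.10
Esfahan,stroke,15.56,120,8.25
Ahvaz,natural,12.32,1092,100.65
Ahvaz,lc,16.48,12,1.98
Ahvaz,copd,18.91,9,1.59
Ahvaz,alri,22.79,3,3.21
Ahvaz,ihd,17.29,187,26.81
Ahvaz,stroke,18.54,79,11.40
Tabriz,natural,9.92,1573,99.46
Tabriz,lc,12.24,24,2.44
Tabriz,copd,14.58,28,2.92
Tabriz,alri,17.4,4,3.48
Tabriz,ihd,15.98,170,15.69
Tabriz,stroke,16.6,86,7.97
Shiraz,natural,9.42,1291,75.05
Shiraz,lc,11.43,15,1.42
Shiraz,copd,13.73,19,1.78
Shiraz,alri,16.33,3,2.48
Shiraz,ihd,15.71,201,16.81
Shiraz,stroke,16.21,22,10.17
Karaj,natural,8.25,857,45.28
Karaj,lc,9.63,12,1.01
Karaj,copd,11.79,10,0.85
Karaj,alri,13.91,2,1.57
Karaj,ihd,15.07,258,19.79
Karaj,stroke,15.28,63,4.80
Mashhad,natural,8.89,2479,83.23
Mashhad,lc,10.62,9,1.78
Mashhad,copd,12.84,31,1.93
Mashhad,alri,15.22,5,1.73
Mashhad,ihd,15.42,332,17.58
Mashhad,stroke,15.78,197,10.41
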