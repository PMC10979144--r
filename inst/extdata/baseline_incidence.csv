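city,endpoint,age_group,baseline_incidence,crf
Arak,natural,30+,966.0,allcause_loglin
Arak,copd,30+,18.73,ier_copd
Arak,lc,30+,15.60,ier_lc
Arak,ihd,25+,157.45,ier_ihd
Arak,stroke,25+,85.46,ier_stroke
Arak,alri,0-5,13.24,ier_alri
Esfahan,natural,30+,777.40,allcause_loglin
Esfahan,copd,30+,12.63,ier_copd
Esfahan,lc,30+,9.62,ier_lc
Esfahan,ihd,25+,125.13,ier_ihd
Esfahan,stroke,25+,53.05,ier_stroke
Esfahan,alri,0-5,23.89,ier_alri
Ahvaz,natural,30+,817.0,allcause_loglin
Ahvaz,copd,30+,8.39,ier_copd
Ahvaz,lc,30+,12.01,ier_lc
Ahvaz,ihd,25+,155.06,ier_ihd
Ahvaz,stroke,25+,61.5,ier_stroke
Ahvaz,alri,0-5,14.09,ier_alri
Tabriz,natural,30+,1003.0,allcause_loglin
Tabriz,copd,30+,20.0,ier_copd
Tabriz,lc,30+,19.97,ier_lc
Tabriz,ihd,25+,98.18,ier_ihd
Tabriz,stroke,25+,48.0,ier_stroke
Tabriz,alri,0-5,20.0,ier_alri
Shiraz,natural,30+,797.0,allcause_loglin
Shiraz,copd,30+,13.0,ier_copd
Shiraz,lc,30+,12.46,ier_lc
Shiraz,ihd,25+,107.0,ier_ihd
Shiraz,stroke,25+,62.77,ier_stroke
Shiraz,alri,0-5,15.21,ier_alri
Karaj,natural,30+,549.0,allcause_loglin
Karaj,copd,30+,7.17,ier_copd
Karaj,lc,30+,10.52,ier_lc
Karaj,ihd,25+,131.33,ier_ihd
Karaj,stroke,25+,31.42,ier_stroke
Karaj,alri,0-5,11.28,ier_alri
Mashhad,natural,30+,936.4,allcause_loglin
Mashhad,copd,30+,15.06,ier_copd
Mashhad,lc,30+,16.8,ier_lc
Mashhad,ihd,25+,114.0,ier_ihd
Mashhad,stroke,25+,65.93,ier_stroke
Mashhad,alri,0-5,11.34,ier_alri
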