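city,n_total,n_30plus,n_25plus,n_under5
Arak,600000,300000,350000,45000
Esfahan,2000000,1000000,1150000,150000
Ahvaz,1300000,650000,750000,100000
Tabriz,1600000,800000,900000,120000
Shiraz,1900000,950000,1050000,140000
Karaj,1600000,800000,900000,120000
Mashhad,3000000,1500000,1700000,220000
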