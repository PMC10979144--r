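city,variable,max,min,mean,sd
Arak,pm25,73.92,7.54,24.12,6.35
Esfahan,pm25,84.02,11.01,27.93,8.79
Ahvaz,pm25,170.69,14.94,43.33,19.23
Tabriz,pm25,87.45,6.5,32.80,17.86
Shiraz,pm25,81.33,10.85,30.85,16.87
Karaj,pm25,84.42,9.91,26.75,11.51
Mashhad,pm25,86.49,14.28,28.57,9.11
Arak,tmpf,32.75,-7.66,15.28,10.47
Esfahan,tmpf,33.62,-2.72,18.85,9.54
Ahvaz,tmpf,43.52,6.04,29.07,10.08
Tabriz,tmpf,33.95,-9.18,13.29,10.58
Shiraz,tmpf,35.42,1.57,19.12,9.47
Karaj,tmpf,37.06,-5.89,16.59,10.66
Mashhad,tmpf,34.43,-3.4,16.06,9.69
Arak,relh,90.05,26.4,64.45,17.67
Esfahan,relh,81.98,24.94,55.65,14.45
Ahvaz,relh,110.35,56.62,92.57,14.31
Tabriz,relh,94.77,39.65,66.14,14.17
Shiraz,relh,95.76,51.31,78.50,11.61
Karaj,relh,98.71,41.51,75.71,13.02
Mashhad,relh,96.1,38.51,73.70,12.96
Arak,drct,54.8,17.6,38.93,6.80
Esfahan,drct,51.95,1.21,27.73,11.67
Ahvaz,drct,69.95,30.13,49.30,7.34
Tabriz,drct,56.37,23.3,40.65,7.33
Shiraz,drct,54.69,8.6,31.01,8.47
Karaj,drct,55.8,11.87,37.73,9.02
Mashhad,drct,55.31,20.86,37.74,6.99
Arak,sknt,100,15.93,46.93,22.67
Esfahan,sknt,80.83,0,40.07,16.47
Ahvaz,sknt,83.32,9.45,28.32,14
Tabriz,sknt,83.04,14.38,44.89,15.73
Shiraz,sknt,90.26,7.1,26.86,17.14
Karaj,sknt,95.64,10.21,30.99,14.42
Mashhad,sknt,94.67,12.26,34.24,20.35
Arak,p01i,335,0,171.66,68.17
Esfahan,p01i,282.91,110,189.04,40.31
Ahvaz,p01i,321.27,79.78,242.42,52.28
Tabriz,p01i,272.82,70.9,142.12,41.58
Shiraz,p01i,253.28,42.06,132.83,42.19
Karaj,p01i,332.5,85.26,214.40,67.84
Mashhad,p01i,270.4,72.97,133.53,36.48
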