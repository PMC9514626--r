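population,variable,category,trd_n,trd_pct,nontrd_n,nontrd_pct
mdd,sex,Women,19407,64.3,103030,61.5
mdd,sex,Men,10755,35.7,64423,38.5
mdd,age_group,18-24,2523,8.4,21349,12.7
mdd,age_group,25-44,10078,33.4,54519,32.6
mdd,age_group,45-64,9396,31.2,41350,24.7
mdd,age_group,65-84,6970,23.1,38135,22.8
mdd,age_group,85+,1195,4.0,12100,7.2
mdd,education,basic,11267,37.4,66174,39.5
mdd,education,medium,11942,39.6,60156,35.9
mdd,education,high,4572,15.2,22851,13.6
mdd,education,unknown,2381,7.9,18272,10.9
mdd,cohabiting,no,13752,45.6,88708,53.0
mdd,cohabiting,yes,16277,54.0,77465,46.3
mdd,cohabiting,unknown,133,0.4,1280,0.8
mdd,year_group,1996-2000,4681,15.5,27806,16.6
mdd,year_group,2001-2005,7532,25.0,39682,23.7
mdd,year_group,2006-2010,9593,31.8,48973,29.2
mdd,year_group,2011-2015,8356,27.7,50992,30.5
mdd,severity,mild,12225,40.5,100160,59.8
mdd,severity,moderate,11407,37.8,49705,29.7
mdd,severity,severe,6530,21.6,17588,10.5
matched,sex,Women,16546,65.3,33089,65.3
matched,sex,Men,8775,34.7,17549,34.7
matched,age_group,18-24,2167,8.6,4334,8.6
matched,age_group,25-44,9081,35.9,18162,35.9
matched,age_group,45-64,8292,32.7,16583,32.7
matched,age_group,65-84,5054,20.0,10106,20.0
matched,age_group,85+,727,2.9,1453,2.9
matched,education,basic,9373,37.0,19115,37.7
matched,education,medium,10272,40.6,19451,38.4
matched,education,high,3960,15.6,8085,16.0
matched,education,unknown,1716,6.8,3987,7.9
matched,cohabiting,no,11284,44.6,24654,48.7
matched,cohabiting,yes,13930,55.0,25583,50.5
matched,cohabiting,unknown,107,0.4,401,0.8
matched,year_group,1996-2000,3860,15.2,7720,15.2
matched,year_group,2001-2005,6313,24.9,12625,24.9
matched,year_group,2006-2010,8018,31.7,16035,31.7
matched,year_group,2011-2015,7130,28.2,14258,28.2
matched,severity,mild,10034,39.6,20068,39.6
matched,severity,moderate,9962,39.3,19924,39.3
matched,severity,severe,5325,21.0,10646,21.0
matched,anxiety,yes,7898,31.2,14646,28.9
matched,substance_abuse,yes,3345,13.2,7424,14.7
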