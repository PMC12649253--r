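block,term,est,se,trr,cl_low,cl_high,sig
onset,residence,-0.1660,0.0812,0.8471,0.7224,0.9932,*
onset,sex,0.4026,0.0568,1.4957,1.3382,1.6717,**
onset,age,0.0000,,,,,
onset,education,0.0000,,,,,
onset,marital,-0.0500,0.0683,0.9512,0.8321,1.0874,
onset,retired,-0.2354,0.1050,0.7903,0.6432,0.9709,*
onset,income,-0.6536,0.2866,0.5201,0.2966,0.9122,*
onset,n_conditions,0.0000,,,,,
onset,pain,0.3875,0.0606,1.4733,1.3083,1.6590,**
onset,badl,0.4671,0.1537,1.5954,1.1805,2.1561,*
onset,social,-0.1310,0.0543,0.8772,0.7886,0.9757,*
onset,child_contact,0.0000,,,,,
onset,child_support,0.0000,,,,,
onset,education_x_income,-0.5862,0.1144,0.5564,0.4446,0.6963,**
onset,n_conditions_x_income,1.4512,0.3113,4.2681,2.3188,7.8560,**
onset,n_conditions_x_sex,0.0000,,,,,
onset,sex_x_age,0.0000,,,,,
onset,age_x_education,0.0000,,,,,
persistence,residence,-0.0723,0.1490,0.9302,0.6946,1.2457,
persistence,sex,0.0000,,,,,
persistence,age,-0.4992,0.3999,0.6070,0.2772,1.3292,
persistence,education,0.0000,,,,,
persistence,marital,-0.0514,0.1238,0.9499,0.7453,1.2106,
persistence,retired,0.0000,,,,,
persistence,income,0.6114,0.5605,1.8430,0.6143,5.5291,
persistence,n_conditions,0.2197,0.7518,1.2457,0.2854,5.4364,
persistence,pain,0.0000,,,,,
persistence,badl,0.0000,,,,,
persistence,social,0.0000,,,,,
persistence,child_contact,0.0000,,,,,
persistence,child_support,-0.0811,0.1157,0.9221,0.7350,1.1569,
persistence,education_x_income,-0.3622,0.2571,0.6962,0.4206,1.1523,
persistence,n_conditions_x_income,0.0000,,,,,
persistence,n_conditions_x_sex,-0.0814,0.5722,0.9218,0.3003,2.8294,
persistence,sex_x_age,0.5098,0.4215,1.6649,0.7288,3.8037,
persistence,age_x_education,0.0000,,,,,
remission,residence,0.0000,,,,,
remission,sex,0.0000,,,,,
remission,age,0.4673,0.2986,1.5956,0.8887,2.8648,
remission,education,0.0000,,,,,
remission,marital,0.0821,0.1038,1.0855,0.8857,1.3303,
remission,retired,0.0000,,,,,
remission,income,-0.1472,0.7786,0.8631,0.1876,3.9703,
remission,n_conditions,-0.1212,1.0128,0.8859,0.1217,6.4490,
remission,pain,0.0000,,,,,
remission,badl,0.0000,,,,,
remission,social,0.0415,0.0811,1.0424,0.8892,1.2220,
remission,child_contact,0.0000,,,,,
remission,child_support,0.0000,,,,,
remission,education_x_income,0.1478,0.5211,1.1593,0.4175,3.2194,
remission,n_conditions_x_income,0.0000,,,,,
remission,n_conditions_x_sex,-0.2723,0.5577,0.7616,0.2553,2.2720,
remission,sex_x_age,-0.3908,0.3525,0.6765,0.3390,1.3501,
remission,age_x_education,0.0000,,,,,
relapse,residence,-0.3314,0.3035,0.7179,0.3961,1.3014,
relapse,sex,0.0000,,,,,
relapse,age,-1.0178,0.6924,0.3614,0.0930,1.4039,
relapse,education,0.0000,,,,,
relapse,marital,0.0000,,,,,
relapse,retired,-0.4200,0.4482,0.6570,0.2729,1.5817,
relapse,income,0.0000,,,,,
relapse,n_conditions,0.0000,,,,,
relapse,pain,0.0000,,,,,
relapse,badl,-0.2841,0.5022,0.7527,0.2813,2.0144,
relapse,social,-0.0987,0.1900,0.9061,0.6244,1.3148,
relapse,child_contact,0.0000,,,,,
relapse,child_support,0.0000,,,,,
relapse,education_x_income,0.0000,,,,,
relapse,n_conditions_x_income,0.0000,,,,,
relapse,n_conditions_x_sex,0.0000,,,,,
relapse,sex_x_age,1.5215,0.6106,4.5790,1.3835,15.1549,*
relapse,age_x_education,0.0000,,,,,
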