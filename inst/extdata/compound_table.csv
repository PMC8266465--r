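no,name,formula,rt_min,mz_mcooh,mz_mh,ms2,is_standard,mass_typo
1,20-Glc-ginsenoside Rf,C48H82O19,1.05,1007.5447,961.5384,799.4883;637.4325;475.3785,0,0
2,Notoginsenoside R1,C47H80O18,1.17,977.5344,931.5288,799.4872;637.4320;475.3792,0,0
3,Ginsenoside Rg1,C42H72O14,1.42,845.4910,799.4869,637.4324;475.3803,1,0
4,Ginsenoside Re,C48H82O18,1.46,991.5502,945.5451,799.4931;783.4944;637.4338;475.3784,1,0
5,Ginsenoside Rf,C42H72O14,4.05,845.4898,799.4855,637.4332;475.3791,1,0
6,Ginsenoside Ra3,C59H100O27,4.33,1285.6436,1239.6372,1107.6023;945.5419;783.4863;621.4360,0,0
7,Ginsenoside F3/F5,C41H70O13,4.48,815.4810,769.4754,637.4333;475.3789,0,0
8,Ginsenoside Rh1,C36H62O9,4.96,683.4381,637.4322,475.3778,1,0
9,Ginsenoside Rg2,C42H72O13,5.03,829.4963,783.4898,637.4306;475.3807,1,0
10,Ginsenoside Ra2,C58H98O26,5.23,1255.6328,1209.6276,1077.5858;945.5414;783.4915;621.4380;459.3847,0,0
11,Ginsenoside Rb1,C54H92O23,5.40,1153.6014,1107.5956,945.5421;783.4899;621.4374;459.3840,1,0
12,Ginsenoside Rc,C53H90O22,6.06,1123.5912,1077.5854,945.5413;783.4907;621.4377;459.3847,1,0
13,Ginsenoside Ra2-isomer,C58H98O26,6.27,1255.6329,1209.6266,1077.5870;945.5418;783.4917;459.3863,0,0
14,Ginsenoside Ro,C48H76O19,6.44,NA,955.4915,793.4398;631.3837;455.3540,0,0
15,Ginsenoside F1,C36H62O9,6.64,683.4385,637.4288,475.3827,1,0
16,Ginsenoside Ra1,C58H98O26,6.68,1255.6334,1209.6271,1077.5790;783.4831;621.4320,0,0
17,Ginsenoside Rb2,C53H90O22,7.09,1123.5912,1077.5859,945.5415;783.4908;621.4387;459.3847,1,0
18,Ginsenoside Rb3,C53H90O22,7.48,1123.5916,1077.5838,945.5406;783.4916;621.4372;459.3855,1,0
19,Ginsenoside Ra1-isomer,C58H98O26,8.03,1255.6338,1209.6284,1077.5868;945.5466;783.4907;621.4337;459.3868,0,0
20,Chikusetsusaponin Iva,C42H66O14,8.91,NA,793.4395,631.3858;455.3555,0,0
21,Ginsenoside Rd,C48H82O18,9.21,991.5497,945.5438,783.4911;621.4377;459.3850,1,0
22,Gypenoside XVII,C48H82O18,10.01,991.5506,945.5432,783.4890;621.4405,1,0
23,Notoginsenoside Fe,C47H80O17,10.74,961.5374,915.5348,783.4901;621.4399;459.3845,1,0
24,Compound O,C47H80O17,11.17,961.5401,915.5327,783.4915;621.4379;459.3847,1,0
25,Notoginsenoside Fd,C47H80O17,11.54,961.5401,915.5330,783.4908;621.4370;459.3854,1,0
26,Ginsenoside Rg6,C42H70O12,12.09,811.4872,765.4798,619.4215,0,0
27,Ginsenoside Rk3,C36H60O8,12.51,665.4287,619.3349,,0,1
28,Ginsenoside F4,C42H70O12,12.90,811.4871,765.4786,619.4219;457.3643,0,0
29,Ginsenoside Rh4,C36H60O8,13.24,665.4284,619.3344,,0,1
30,Ginsenoside F2,C42H72O13,13.62,829.4974,783.4861,621.4400;459.3816,1,0
31,PPT,C30H52O4,14.69,521.3853,475.3792,,1,0
32,Glycoside D3a,C42H66O14,14.70,NA,793.4392,613.3735;455.3517,0,0
33,Gypenoside LXXV,C42H72O13,15.51,829.4975,783.4913,621.4393;459.3844,1,0
34,Ginsenoside Rg3,C42H72O13,15.79,829.4951,783.4912,621.4393;459.3845,1,0
35,20(R)-Rg3,C42H72O13,16.28,829.4974,783.4905,621.4382;459.3864,0,0
36,Ginsenoside Mc,C41H70O12,17.31,799.4866,753.4793,621.4371;459.3869,1,0
37,Compound Y,C41H70O12,17.94,799.4868,753.4804,621.4374;459.3866,1,0
38,Compound Mx,C41H70O12,18.42,799.4869,753.4770,621.4406;459.3858,1,0
39,Compound K,C36H62O8,19.30,667.4473,621.4392,459.3828,1,0
40,Ginsenoside Rk1,C42H70O12,19.46,811.4865,765.4803,603.4224,0,0
41,Ginsenoside Rg5,C42H70O12,19.55,811.4869,765.4843,603.4230,0,0
42,Ginsenoside Rh2,C36H62O8,19.59,667.4438,621.4372,459.3831,1,0
43,PPD,C30H52O3,20.99,505.3909,459.3843,,1,0
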