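name,fx_10,fx_20,fx_50,fx_100,fx_200,mean_fx,rsd
Rb2,1.00,1.00,1.00,1.00,1.00,NA,NA
Rg1,0.32,0.30,0.31,0.30,0.30,0.31,2.92
Re,0.48,0.46,0.47,0.48,0.46,0.47,2.13
Rf,0.48,0.48,0.52,0.48,0.50,0.49,3.64
Rb1,3.45,3.25,3.05,3.18,3.22,3.23,4.48
Rg2,0.44,0.43,0.46,0.42,0.42,0.43,3.86
Rh1,0.09,0.09,0.09,0.09,0.08,0.09,5.08
Rc,0.93,0.88,0.94,0.94,0.92,0.92,2.70
F1,0.07,0.08,0.08,0.08,0.08,0.08,2.83
Rb3,0.97,0.97,0.98,0.99,0.98,0.98,0.86
Rd,0.36,0.34,0.35,0.34,0.34,0.35,2.59
GXVII,0.24,0.24,0.25,0.23,0.24,0.24,2.95
nFe,0.62,0.67,0.66,0.69,0.68,0.66,4.07
CO,0.60,0.62,0.63,0.66,0.65,0.63,3.78
nFd,1.05,1.00,1.05,0.99,1.05,1.03,2.95
F2,0.10,0.10,0.09,0.10,0.10,0.10,4.56
G75,0.09,0.09,0.09,0.08,0.09,0.09,5.08
Rg3,0.14,0.14,0.14,0.13,0.14,0.14,3.24
PPT,1.00,0.97,0.95,0.99,1.01,0.98,2.45
Mc,0.33,0.34,0.34,0.36,0.34,0.34,3.20
CY,0.47,0.48,0.50,0.49,0.47,0.48,2.71
CMx,0.24,0.25,0.25,0.26,0.25,0.25,2.83
CK,0.14,0.13,0.14,0.15,0.14,0.14,5.05
Rh2,0.06,0.07,0.07,0.07,0.07,0.07,3.24
PPD,6.48,6.95,6.67,6.98,6.45,6.71,3.75
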