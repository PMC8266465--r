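name,formula,rt_min,class,slope,intercept,range_low,range_high,loss_seq
Rg1,C42H72O14,1.46,PPT,64984,980287,20,2000,Glc;Glc
Re,C48H82O18,1.46,PPT,41225.1,688583,20,2000,Rha;Glc;Glc
Rf,C42H72O14,4.08,PPT,42146.9,-44017.1,10,500,Glc;Glc
Rh1,C36H62O9,5.02,PPT,238413,-153145,2,200,Glc
Rb1,C54H92O23,5.44,PPD,6240.95,85602.4,20,2000,Glc;Glc;Glc;Glc
Rg2,C42H72O13,5.08,PPT,52298.5,-612776,50,1000,Rha;Glc
Rc,C53H90O22,6.09,PPD,22275,-24796.1,10,1000,Pen;Glc;Glc;Glc
F1,C36H62O9,6.73,PPT,292355,-175557,2,200,Glc
Rb2,C53H90O22,7.13,PPD,20778.7,-36514.3,10,1000,Pen;Glc;Glc;Glc
Rb3,C53H90O22,7.59,PPD,20695.1,48835.8,50,2000,Pen;Glc;Glc;Glc
Rd,C48H82O18,9.25,PPD,61029.8,-558838,100,2000,Glc;Glc;Glc
GXVII,C48H82O18,10.07,PPD,85248.5,-57819.7,2,200,Glc;Glc;Glc
nFe,C47H80O17,10.8,PPD,29919.9,-7299.02,2,200,Pen;Glc;Glc
CO,C47H80O17,11.61,PPD,31396.7,-13591.7,1,200,Pen;Glc;Glc
nFd,C47H80O17,12.01,PPD,20835.8,-25094.8,10,200,Pen;Glc;Glc
F2,C42H72O13,13.68,PPD,212189,-115446,2,200,Glc;Glc
G75,C42H72O13,15.63,PPD,231218,-99660.6,1,200,Glc;Glc
Rg3,C42H72O13,15.89,PPD,149379,-82845.1,2,200,Glc;Glc
PPT,C30H52O4,14.75,PPT,27249.2,-50845.3,2,50,
Mc,C41H70O12,17.29,PPD,58309.3,-14125.5,1,200,Pen;Glc
CY,C41H70O12,18.02,PPD,41233.6,36194,1,200,Pen;Glc
CMx,C41H70O12,18.46,PPD,80902.7,-22662.5,2,200,Pen;Glc
CK,C36H62O8,19.31,PPD,140955,96724.4,1,200,Glc
Rh2,C36H62O8,19.6,PPD,316346,-188172,2,200,Glc
PPD,C30H52O3,20.99,PPD,3099.89,-4843.21,2,200,
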