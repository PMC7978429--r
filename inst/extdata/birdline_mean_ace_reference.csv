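joint,dof,mtu,mean_ace
hip,FLEXEX,CFL,-0.25
hip,FLEXEX,CFB,-0.19
hip,FLEXEX,ILFB,-0.21
hip,FLEXEX,ADD1,-0.19
hip,FLEXEX,ADD2,-0.24
hip,FLEXEX,FTI1,-0.31
hip,FLEXEX,FTI3,-0.16
hip,FLEXEX,FTE,-0.31
hip,FLEXEX,IT3,-0.11
hip,FLEXEX,ISTR,-0.028
hip,FLEXEX,IFE,-0.027
hip,FLEXEX,ITC,-0.0089
hip,FLEXEX,AMB,0.12
hip,FLEXEX,IT1,0.25
hip,FLEXEX,IT2,0.095
hip,FLEXEX,PIFE1,0.089
hip,FLEXEX,PIFE2,0.089
hip,FLEXEX,PIFE3,0.022
hip,FLEXEX,PIFI1,0.079
hip,FLEXEX,PIFI2,0.062
hip,ABAD,CFL,0.011
hip,ABAD,ADD1,0.18
hip,ABAD,ADD2,0.13
hip,ABAD,FTI1,0.18
hip,ABAD,FTI3,0.046
hip,ABAD,ISTR,0.074
hip,ABAD,PIFE1,0.087
hip,ABAD,PIFE2,0.086
hip,ABAD,PIFE3,0.088
hip,ABAD,CFB,-0.044
hip,ABAD,ILFB,-0.11
hip,ABAD,FTE,-0.074
hip,ABAD,AMB,-0.013
hip,ABAD,IT1,-0.086
hip,ABAD,IT2,-0.15
hip,ABAD,IT3,-0.16
hip,ABAD,PIFI1,-0.045
hip,ABAD,PIFI2,-0.019
hip,ABAD,IFE,-0.13
hip,ABAD,ITC,-0.079
hip,LAR,ADD1,0.0061
hip,LAR,FTI3,0.0057
hip,LAR,FTE,0.021
hip,LAR,PIFI1,0.038
hip,LAR,PIFI2,0.090
hip,LAR,ITC,0.069
hip,LAR,CFL,-0.037
hip,LAR,CFB,-0.039
hip,LAR,ILFB,-0.0072
hip,LAR,ADD2,-0.011
hip,LAR,FTI1,-0.011
hip,LAR,ISTR,-0.12
hip,LAR,AMB,-0.0060
hip,LAR,IT1,-0.021
hip,LAR,IT2,-0.026
hip,LAR,IT3,-0.045
hip,LAR,PIFE1,-0.027
hip,LAR,PIFE2,-0.040
hip,LAR,PIFE3,-0.10
hip,LAR,IFE,-0.020
knee,FLEXEX,AMB,0.068
knee,FLEXEX,IT1,0.090
knee,FLEXEX,IT2,0.080
knee,FLEXEX,IT3,0.070
knee,FLEXEX,FMTI,0.069
knee,FLEXEX,FMTE,0.071
knee,FLEXEX,EDL,0.032
knee,FLEXEX,TA,0.0020
knee,FLEXEX,ILFB,-0.10
knee,FLEXEX,FTI1,-0.091
knee,FLEXEX,FTI3,-0.098
knee,FLEXEX,FTE,-0.10
knee,FLEXEX,GL,-0.066
knee,FLEXEX,FDL,-0.063
knee,FLEXEX,FHL,-0.064
ankle,FLEXEX,EDL,0.098
ankle,FLEXEX,EHL,0.054
ankle,FLEXEX,TA,0.10
ankle,FLEXEX,FB,0.034
ankle,FLEXEX,AMB,-0.12
ankle,FLEXEX,GL,-0.16
ankle,FLEXEX,GM,-0.15
ankle,FLEXEX,FDL,-0.12
ankle,FLEXEX,FHL,-0.12
ankle,FLEXEX,FL,-0.028
ankle,FLEXEX,FLT,-0.094
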