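region,side,mean,sd,min,max,pct_variation,rel_mean,rel_sd,F_value,p_printed
Brain,total,0.522,0.038,0.425,0.628,32.27,NA,NA,1.018,0.428
AL,total,0.0284,0.0033,0.0201,0.0365,44.97,5.43,0.47,5.055,<0.001
AL,left,0.0142,0.0017,0.0095,0.0183,47.76,NA,NA,NA,NA
AL,right,0.0141,0.0018,0.0096,0.0182,47.49,NA,NA,NA,NA
MB,total,0.134,0.011,0.098,0.170,42.30,25.68,1.75,2.315,0.025
MB,left,0.066,0.007,0.030,0.075,60.25,NA,NA,NA,NA
MB,right,0.065,0.005,0.048,0.073,34.26,NA,NA,NA,NA
OL,total,0.190,0.014,0.161,0.228,29.41,36.48,1.66,4.368,0.200
OL,left,0.095,0.007,0.082,0.112,27.46,NA,NA,NA,NA
OL,right,0.095,0.007,0.080,0.116,31.29,NA,NA,NA,NA
ME,total,0.146,0.011,0.122,0.174,29.95,27.90,1.33,2.819,0.288
ME,left,0.073,0.006,0.062,0.085,27.52,NA,NA,NA,NA
ME,right,0.073,0.005,0.060,0.089,32.29,NA,NA,NA,NA
LO,total,0.045,0.004,0.038,0.054,29.94,8.58,0.43,2.733,0.009
LO,left,0.0223,0.002,0.0179,0.027,33.96,NA,NA,NA,NA
LO,right,0.0224,0.002,0.0185,0.027,30.72,NA,NA,NA,NA
CX,total,0.0033,0.0004,0.0021,0.0043,51.74,0.63,0.07,1.839,0.400
OTH,total,0.166,0.019,0.100,0.203,50.61,31.78,2.06,1.643,0.433
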