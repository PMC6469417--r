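nuclear_background,haplotype,phase,cage,s_cage,se_cage,S_overall,se_S,ci_low,ci_high,v_r,lrt_p
OreR,OreR,pre,1,-0.102,0.051,-0.052,0.020,-0.092,-0.012,<0.001,0.91
OreR,OreR,pre,2,-0.026,0.030,-0.052,0.020,-0.092,-0.012,<0.001,0.91
OreR,OreR,pre,3,-0.054,0.028,-0.052,0.020,-0.092,-0.012,<0.001,0.91
OreR,OreR,pre,4,-0.028,0.046,-0.052,0.020,-0.092,-0.012,<0.001,0.91
OreR,OreR,post,1,-0.046,0.062,-0.001,0.019,-0.054,0.054,0.63,0.049
OreR,OreR,post,2,0.007,0.006,-0.001,0.019,-0.054,0.054,0.63,0.049
OreR,OreR,post,3,0.010,0.056,-0.001,0.019,-0.054,0.054,0.63,0.049
OreR,OreR,post,4,0.024,0.010,-0.001,0.019,-0.054,0.054,0.63,0.049
Aut,OreR,pre,1,-0.047,0.030,-0.028,0.011,-0.055,-0.003,0.55,0.003
Aut,OreR,pre,2,0.025,0.010,-0.028,0.011,-0.055,-0.003,0.55,0.003
Aut,OreR,pre,3,-0.019,0.006,-0.028,0.011,-0.055,-0.003,0.55,0.003
Aut,OreR,pre,4,-0.071,0.012,-0.028,0.011,-0.055,-0.003,0.55,0.003
Aut,OreR,post,1,-0.027,0.007,-0.010,0.011,-0.042,0.022,0.62,0.053
Aut,OreR,post,2,-0.042,0.012,-0.010,0.011,-0.042,0.022,0.62,0.053
Aut,OreR,post,3,0.013,0.006,-0.010,0.011,-0.042,0.022,0.62,0.053
Aut,OreR,post,4,0.015,0.028,-0.010,0.011,-0.042,0.022,0.62,0.053
OreR,mau12,pre,1,-0.161,0.057,-0.106,0.025,-0.156,-0.056,<0.001,1.0
OreR,mau12,pre,2,-0.155,0.016,-0.106,0.025,-0.156,-0.056,<0.001,1.0
OreR,mau12,pre,3,-0.024,0.022,-0.106,0.025,-0.156,-0.056,<0.001,1.0
OreR,mau12,pre,4,-0.085,0.075,-0.106,0.025,-0.156,-0.056,<0.001,1.0
OreR,mau12,post,1,0.037,0.030,-0.085,0.040,-0.185,0.009,0.37,0.28
OreR,mau12,post,2,-0.242,0.050,-0.085,0.040,-0.185,0.009,0.37,0.28
OreR,mau12,post,3,-0.096,0.007,-0.085,0.040,-0.185,0.009,0.37,0.28
OreR,mau12,post,4,-0.039,0.016,-0.085,0.040,-0.185,0.009,0.37,0.28
OreR,siI,pre,1,0.058,0.019,0.062,0.010,0.042,0.084,0.29,0.11
OreR,siI,pre,2,0.079,0.022,0.062,0.010,0.042,0.084,0.29,0.11
OreR,siI,pre,3,0.037,0.018,0.062,0.010,0.042,0.084,0.29,0.11
OreR,siI,pre,4,0.074,0.021,0.062,0.010,0.042,0.084,0.29,0.11
OreR,siI,post,1,-0.003,0.001,-0.000,0.018,-0.055,0.051,0.64,0.04
OreR,siI,post,2,0.063,0.027,-0.000,0.018,-0.055,0.051,0.64,0.04
OreR,siI,post,3,-0.004,0.033,-0.000,0.018,-0.055,0.051,0.64,0.04
OreR,siI,post,4,-0.057,0.002,-0.000,0.018,-0.055,0.051,0.64,0.04
OreR,sm21,pre,1,0.030,0.046,-0.044,0.020,-0.085,-0.0004,0.28,0.11
OreR,sm21,pre,2,-0.109,0.035,-0.044,0.020,-0.085,-0.0004,0.28,0.11
OreR,sm21,pre,3,-0.031,0.014,-0.044,0.020,-0.085,-0.0004,0.28,0.11
OreR,sm21,pre,4,-0.068,0.034,-0.044,0.020,-0.085,-0.0004,0.28,0.11
OreR,sm21,post,1,-0.008,0.009,0.025,0.037,-0.053,0.105,<0.001,0.85
OreR,sm21,post,2,-0.089,0.044,0.025,0.037,-0.053,0.105,<0.001,0.85
OreR,sm21,post,3,0.136,0.077,0.025,0.037,-0.053,0.105,<0.001,0.85
OreR,sm21,post,4,0.062,0.022,0.025,0.037,-0.053,0.105,<0.001,0.85
Aut,mau12,pre,1,0.017,0.034,0.013,0.019,-0.026,0.052,<0.001,1.0
Aut,mau12,pre,2,0.043,0.052,0.013,0.019,-0.026,0.052,<0.001,1.0
Aut,mau12,pre,3,0.041,0.034,0.013,0.019,-0.026,0.052,<0.001,1.0
Aut,mau12,pre,4,-0.050,0.029,0.013,0.019,-0.026,0.052,<0.001,1.0
Aut,mau12,post,1,0.023,0.010,0.017,0.019,-0.033,0.066,0.39,0.25
Aut,mau12,post,2,0.006,0.084,0.017,0.019,-0.033,0.066,0.39,0.25
Aut,mau12,post,3,0.001,0.026,0.017,0.019,-0.033,0.066,0.39,0.25
Aut,mau12,post,4,0.039,0.043,0.017,0.019,-0.033,0.066,0.39,0.25
Aut,siI,pre,1,-0.037,0.030,-0.029,0.018,-0.064,0.009,<0.001,0.72
Aut,siI,pre,2,-0.024,0.030,-0.029,0.018,-0.064,0.009,<0.001,0.72
Aut,siI,pre,3,-0.074,0.051,-0.029,0.018,-0.064,0.009,<0.001,0.72
Aut,siI,pre,4,0.019,0.014,-0.029,0.018,-0.064,0.009,<0.001,0.72
Aut,siI,post,1,-0.179,0.013,-0.083,0.024,-0.143,-0.018,0.48,0.15
Aut,siI,post,2,-0.048,0.025,-0.083,0.024,-0.143,-0.018,0.48,0.15
Aut,siI,post,3,-0.049,0.014,-0.083,0.024,-0.143,-0.018,0.48,0.15
Aut,siI,post,4,-0.055,0.048,-0.083,0.024,-0.143,-0.018,0.48,0.15
Aut,sm21,pre,1,0.064,0.118,0.022,0.034,-0.051,0.090,0.10,0.55
Aut,sm21,pre,2,-0.020,0.070,0.022,0.034,-0.051,0.090,0.10,0.55
Aut,sm21,pre,3,0.031,0.046,0.022,0.034,-0.051,0.090,0.10,0.55
Aut,sm21,pre,4,0.014,0.025,0.022,0.034,-0.051,0.090,0.10,0.55
Aut,sm21,post,1,0.037,0.006,0.033,0.010,0.013,0.054,<0.001,0.84
Aut,sm21,post,2,0.031,0.021,0.033,0.010,0.013,0.054,<0.001,0.84
Aut,sm21,post,3,0.050,0.037,0.033,0.010,0.013,0.054,<0.001,0.84
Aut,sm21,post,4,0.015,0.004,0.033,0.010,0.013,0.054,<0.001,0.84
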