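series,level,label,P_NMDA,P_GABA,P_AMPA,g_Ks
A,1,A1,1.64,3.98,1.22,0.97
A,2,A2,1.43,4.61,1.22,0.97
A,3,A3,1.12,8.51,1.22,0.97
A,4,A4,1.07,9.41,1.22,0.97
B,1,B1,1.64,3.98,1.22,0.97
B,2,B2,1.57,5.12,1.22,1.10
B,3,B3,1.42,6.02,1.22,1.24
B,4,B4,1.27,8.13,1.22,1.18
AR,1,AR1,1.07,9.41,1.22,0.81
AR,2,AR2,1.07,9.41,1.22,0.67
AR,3,AR3,1.07,9.41,1.22,0.53
AR,4,AR4,1.07,9.41,1.22,0.40
BR,1,BR1,1.27,8.13,1.22,0.98
BR,2,BR2,1.27,8.13,1.22,0.79
BR,3,BR3,1.27,8.13,1.22,0.60
BR,4,BR4,1.27,8.13,1.22,0.40
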