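structure,parameter,delta_min,delta_max,delta_mean,delta_sd,p_value
PTVnx,D98,-4.7229,-0.5976,-2.5834,2.0669,0.162805
PTVnx,D2,-2.4189,0.7140,-0.6684,1.5985,0.544176
PTVnx,D95,-4.3023,-0.4292,-2.2084,1.9556,0.18964
PTVnx,Dmean,-2.8807,0.3111,-1.1126,1.6235,0.357107
PTVnx,V100,-24.7283,-2.3761,-11.9972,11.4960,0.212409
PTVnx,V95,-2.7742,0.0000,-0.9247,1.6017,0.42265
PTVnx,HI,11.3139,20.2581,16.7608,4.7802,0.0260581
PTVnx,CI,-10.3710,68.4791,27.2364,39.5506,0.355278
PTV1,D98,-4.0781,-0.3058,-1.9883,1.9189,0.214542
PTV1,D2,-2.5865,0.4907,-0.8553,1.5743,0.446024
PTV1,D95,-3.3613,0.1065,-1.4590,1.7583,0.287218
PTV1,Dmean,-2.5729,0.5482,-0.8222,1.5949,0.466128
PTV1,V100,-48.2787,-2.1300,-21.0098,24.1911,0.27142
PTV1,V95,-0.4131,0.0000,-0.1377,0.2385,0.42265
PTV1,CI,2.4641,15.0045,7.9867,6.4025,0.163294
PTV2,D98,-21.9136,-8.8058,-15.4395,6.5554,0.0551653
PTV2,D2,-2.7950,0.3066,-1.1104,1.5680,0.344777
PTV2,D95,-12.9296,-3.4616,-7.5596,4.8605,0.114592
PTV2,Dmean,-3.8803,-0.3317,-1.9699,1.7899,0.196878
PTV2,V100,-8.2026,-0.9876,-4.3840,3.6260,0.171274
PTV2,V95,-6.4941,-1.8290,-4.0150,2.3464,0.0974772
PTV2,CI,-6.4941,-1.8290,-4.0150,2.3464,0.0974772
brainstem,D2,-1.8664,0.7895,-0.1736,1.4706,0.856898
spinal_cord,D2,3.2907,131.4032,65.3072,64.1536,0.219921
parotid_l,Dmean,38.7762,295.1545,150.0641,131.4893,0.186707
parotid_r,Dmean,-10.9687,1696.3384,577.9183,969.0348,0.410167
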