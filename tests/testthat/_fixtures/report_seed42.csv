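case,sgac,mgac_uncorrected,mgac_corrected,global_3d,PTVnx,PTV1,PTV2,brainstem,spinal_cord,parotid_l,parotid_r
case_01,92.7536,76.8116,93.4783,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000
case_02,100.0000,89.8551,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000,100.0000
case_03,86.9565,58.6957,86.9565,94.4837,74.9677,84.3294,88.5207,100.0000,100.0000,100.0000,100.0000
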