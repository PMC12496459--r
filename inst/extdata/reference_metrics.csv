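feature,metric,mean_gnn_gru,sd_gnn_gru,mean_gru,sd_gru,d_printed,consistent
l_ankle,mae,0.209,0.047,0.339,0.009,3.842,TRUE
l_ankle,mse,0.080,0.028,0.214,0.011,6.299,TRUE
l_ankle,r2,0.799,0.024,0.424,0.015,18.738,TRUE
l_knee,mae,0.204,0.094,0.440,0.014,3.512,TRUE
l_knee,mse,0.077,0.056,0.324,0.015,6.025,TRUE
l_knee,r2,0.828,0.101,0.127,0.024,9.550,TRUE
l_hip,mae,0.202,0.061,0.314,0.010,2.562,TRUE
l_hip,mse,0.074,0.039,0.194,0.011,4.188,TRUE
l_hip,r2,0.820,0.063,0.477,0.010,7.604,TRUE
r_ankle,mae,0.215,0.096,0.490,0.009,4.033,TRUE
r_ankle,mse,0.090,0.069,0.366,0.016,5.511,TRUE
r_ankle,r2,0.810,0.096,0.114,0.081,8.962,FALSE
r_knee,mae,0.206,0.055,0.455,0.012,6.255,TRUE
r_knee,mse,0.082,0.029,0.334,0.018,10.441,TRUE
r_knee,r2,0.805,0.014,0.199,0.022,38.288,FALSE
r_hip,mae,0.198,0.071,0.401,0.012,3.987,TRUE
r_hip,mse,0.078,0.037,0.287,0.012,7.599,TRUE
r_hip,r2,0.819,0.037,0.226,0.018,20.382,TRUE
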