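feature,domain,loading
dominant_freq,frequency,-0.271
acc_x_min,magnitude,-0.285
acc_x_max,magnitude,0.233
acc_x_sd,magnitude,0.195
acc_y_min,magnitude,-0.286
acc_y_sd,magnitude,0.182
acc_z_min,magnitude,-0.194
acc_z_p75,magnitude,0.209
acc_z_max,magnitude,0.358
acc_z_sd,magnitude,0.440
acc_z_var,magnitude,0.262
angle_x_min,angle,-0.389
angle_x_median,angle,-0.176
angle_x_mean,angle,-0.175
angle_x_max,angle,0.220
angle_x_sd,angle,0.394
angle_y_min,angle,-0.241
angle_y_max,angle,0.169
angle_y_sd,angle,0.329
angle_z_min,angle,-0.183
angle_z_median,angle,0.124
angle_z_mean,angle,0.125
angle_z_max,angle,0.340
angle_z_sd,angle,0.526
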