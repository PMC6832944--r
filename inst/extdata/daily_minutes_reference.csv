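category,clusters,model_mean,model_sd,criterion,criterion_mean,criterion_sd,bias,loa_halfwidth,n
sedentary,A-F,1024.90,67.38,sedentary,1117.54,64.86,-92.6,98.1,8
stand_step,G-H,293.19,63.59,stand_step,280.98,65.22,12.2,132.1,8
high_step,I-J,121.17,38.23,high_step,41.49,32.19,79.7,80.2,8
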