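target,metric,value
SBP,cum_pct_5,80.63
SBP,cum_pct_10,95.86
SBP,cum_pct_15,98.78
DBP,cum_pct_5,90.19
DBP,cum_pct_10,98.29
DBP,cum_pct_15,99.59
SBP,mean_error,3.21
SBP,sd_error,3.35
DBP,mean_error,2.23
DBP,sd_error,2.44
SBP,rmse,4.643
DBP,rmse,3.307
SBP,mae,3.21
DBP,mae,2.23
SBP,pearson_r,0.977
DBP,pearson_r,0.947
SBP,loa_low,-9.38
SBP,loa_high,8.76
DBP,loa_low,-5.97
DBP,loa_high,6.87
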