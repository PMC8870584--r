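channel,truth,pred_hc,pred_pd
Fp1,HC,3042,38
Fp1,PD,19,2967
CP5,HC,3077,3
CP5,PD,2,2984
Fp2,HC,3021,37
Fp2,PD,18,2990
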