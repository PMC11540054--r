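method,body,bladder,rectum,target,reported_mean,reported_sd
iof,10,7.2,6.5,4.3,7.0,2
hybrid,12,13,8.1,7.6,12,2.8
twostep,2.8,2.7,2.9,2.9,2.9,0.8
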