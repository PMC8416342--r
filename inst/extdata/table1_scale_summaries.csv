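scale,grade,mean,sd,n,printed_f
PSS,1,21.0,7.6,123,8.92
PSS,2,19.6,6.2,110,8.92
PSS,3,17.9,6.5,121,8.92
PSS,4,16.6,7.0,100,8.92
GAD7,1,6.6,5.1,123,3.10
GAD7,2,5.5,4.3,110,3.10
GAD7,3,5.0,4.9,121,3.10
GAD7,4,5.0,4.9,100,3.10
PHQ9,1,5.7,4.6,123,4.89
PHQ9,2,4.3,4.5,110,4.89
PHQ9,3,4.0,4.6,121,4.89
PHQ9,4,3.5,4.6,100,4.89
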