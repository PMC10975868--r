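variable,mean1,sd1,n1,mean2,sd2,n2
tt,119.5863,18.5784,8,82.9020,19.5450,5
Nc,63.25,12.80,8,62.20,15.43,5
sigma,0.13013,0.02988,8,0.07240,0.00961,5
t_bar,1.8388,0.2928,8,1.3380,0.1008,5
a_hat,4.21137,1.67834,8,1.79680,1.48083,5
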