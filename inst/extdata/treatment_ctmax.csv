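population,acclim_C,modeled_mean_C,modeled_sd,observed_mean_C,observed_sd,count,capacity_C,capacity_sd
Coleman,11,28.1,0.14,27.9,0.39,22,NA,NA
Coleman,16,29.3,0.15,29.3,0.37,20,1.9,0.17
Coleman,20,30.0,0.15,30.0,0.40,20,NA,NA
Elk River,11,27.9,0.15,28.0,0.45,21,NA,NA
Elk River,16,28.5,0.14,28.5,0.83,20,1.5,0.21
Elk River,20,29.5,0.15,29.1,0.91,19,NA,NA
Feather River,11,27.8,0.13,27.8,0.40,21,NA,NA
Feather River,16,29.0,0.14,29.0,0.53,23,1.1,0.20
Feather River,20,28.9,0.15,28.7,0.81,22,NA,NA
Priest Rapids,11,27.9,0.14,27.9,0.46,23,NA,NA
Priest Rapids,16,28.9,0.18,28.9,0.70,20,1.8,0.19
Priest Rapids,20,29.7,0.16,29.6,0.67,20,NA,NA
Trask River,11,28.0,0.20,28.1,0.43,25,NA,NA
Trask River,16,28.6,0.17,28.4,0.73,20,2.1,0.19
Trask River,20,30.1,0.18,30.0,0.77,18,NA,NA
Trinity River,11,28.4,0.15,28.5,0.18,21,NA,NA
Trinity River,16,28.9,0.15,29.2,0.66,21,0.7,0.19
Trinity River,20,29.2,0.14,29.1,0.97,21,NA,NA
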