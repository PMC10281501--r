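population,acclim_C,rmr_q10,rmr_q10_sd,as_at_topt,as_sd,topt_C,topt_sd,delta_topt_C,delta_topt_sd
Coleman,11,2.50,0.03,8.92,0.09,18.75,0.64,NA,NA
Coleman,16,2.48,0.02,8.98,0.08,20.38,0.48,3.44,1.08
Coleman,20,2.34,0.02,8.76,0.09,22.19,0.89,NA,NA
Elk River,11,2.36,0.03,7.96,0.09,17.45,0.41,NA,NA
Elk River,16,2.67,0.03,8.89,0.10,18.33,0.28,2.69,0.72
Elk River,20,2.23,0.02,7.69,0.09,20.14,0.57,NA,NA
Feather River,11,2.67,0.03,10.96,0.10,20.48,0.69,NA,NA
Feather River,16,2.41,0.03,11.99,0.35,25.95,2.22,-0.91,0.85
Feather River,20,2.20,0.03,7.97,0.10,19.57,0.48,NA,NA
Priest Rapids,11,2.74,0.03,10.47,0.10,20.07,0.58,NA,NA
Priest Rapids,16,2.32,0.03,9.47,0.09,20.51,0.54,2.63,1.24
Priest Rapids,20,2.45,0.03,8.70,0.11,22.71,1.11,NA,NA
Trask River,11,2.34,0.03,7.09,0.09,17.87,0.61,NA,NA
Trask River,16,2.57,0.03,6.99,0.10,17.59,0.33,3.93,1.32
Trask River,20,2.55,0.03,8.11,0.09,21.80,1.18,NA,NA
Trinity River,11,2.29,0.03,8.96,0.10,18.78,0.93,NA,NA
Trinity River,16,2.33,0.02,7.79,0.10,18.82,0.46,4.81,2.56
Trinity River,20,2.40,0.03,7.13,0.19,23.59,2.50,NA,NA
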