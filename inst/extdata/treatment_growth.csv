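population,acclim_C,time_days,growth_g_day,growth_sd,capacity_g_day,capacity_sd
Coleman,11,29,0.16,0.021,NA,NA
Coleman,16,29,0.23,0.026,0.11,0.028
Coleman,20,29,0.27,0.026,NA,NA
Elk River,11,41,0.17,0.023,NA,NA
Elk River,16,26,0.22,0.039,0.04,0.032
Elk River,20,41,0.21,0.025,NA,NA
Feather River,11,42,0.17,0.023,NA,NA
Feather River,16,28,0.17,0.036,0.06,0.042
Feather River,20,28,0.24,0.037,NA,NA
Priest Rapids,11,42,0.13,0.022,NA,NA
Priest Rapids,16,29,0.22,0.035,0.08,0.032
Priest Rapids,20,42,0.21,0.024,NA,NA
Trask River,11,42,0.16,0.023,NA,NA
Trask River,16,37,0.22,0.026,0.02,0.033
Trask River,20,42,0.18,0.026,NA,NA
Trinity River,11,28,0.06,0.032,NA,NA
Trinity River,16,54,0.07,0.018,0.06,0.036
Trinity River,20,54,0.12,0.018,NA,NA
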