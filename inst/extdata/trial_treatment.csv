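subject_id,inoculations,days_on_treatment,ttp_days,dx_to_rx_years,survival_months,tumor_regression,inoculations_s23,days_on_treatment_s23,ttp_days_s23
A001,5,98,128,6,40.7,FALSE,NA,NA,NA
A002,6,117,223,2,33.7,TRUE,13,229,160
A003,5,91,159,33,35.6,FALSE,NA,NA,NA
B001,4,58,64,10,7.0,FALSE,NA,NA,NA
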