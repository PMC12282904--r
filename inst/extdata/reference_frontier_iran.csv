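strategy,cost,qaly,step_icer
No screening,7030.78,17.99,NA
Screening every three years from the age of 50,7085.80,18.01,2675.20
Screening every three years from the age of 40,7192.20,18.03,7373.41
Screening every three years from the age of 30,7301.06,18.04,9466.41
Screening every two years from the age of 30,7442.80,18.04,20466.83
Annual screening from the age of 30,7892.55,18.05,39731.03
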