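strategy,cost,qaly,status
No screening,7030.78,17.99,undominated
Screening every three years from the age of 50,7085.80,18.01,undominated
Screening every two years from the age of 50,7133.10,18.01,extended_dominated
Screening every three years from the age of 40,7192.20,18.03,undominated
Screening every two years from the age of 40,7266.44,18.03,extended_dominated
Annual screening from the age of 50,7262.90,18.02,absolutely_dominated
Screening every three years from the age of 30,7301.06,18.04,undominated
Screening every two years from the age of 30,7442.80,18.04,undominated
Annual screening from the age of 40,7489.57,18.03,absolutely_dominated
Annual screening from the age of 30,7892.55,18.05,undominated
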