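endpoint,weight,PAZ,Derivative-1,Derivative-2,Derivative-3,err1_printed,err2_printed,err3_printed
cei,NA,0.925,0.619,0.578,0.649,NA,NA,NA
convulsive,0.50,74.075,62.218,60.048,63.499,3.23,0.96,4.30
gastrointestinal,0.40,99.890,87.029,85.286,88.230,2.70,2.57,2.20
cardiotoxicity,0.10,93.715,91.282,91.352,91.266,15.07,32.78,12.42
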