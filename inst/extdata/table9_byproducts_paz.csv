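compound,pred59,pred61,pred_avg_printed,rel_change_printed
PAZ,7.048,NA,NA,NA
PAZ-Cl-1,7.448,7.992,7.720,9.53
PAZ-Cl-2,7.719,8.113,7.916,12.32
PAZ-Cl-3,7.806,7.991,7.899,12.07
PAZ-Cl-4,7.588,8.195,7.891,11.96
PAZ-Cl-5,7.378,7.755,7.567,7.36
PAZ-Cl-6,7.275,7.678,7.477,6.09
PAZ-Cl-7,7.149,7.533,7.341,4.16
PAZ-Cl-8,6.967,7.235,7.101,0.75
PAZ-Cl-9,6.829,7.355,7.092,0.62
PAZ-Cl-10,7.497,7.709,7.603,7.87
PAZ-Cl-11,7.481,7.670,7.575,7.48
PAZ-Cl-12,7.415,7.649,7.532,6.87
PAZ-Cl-13,7.375,7.572,7.473,6.03
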