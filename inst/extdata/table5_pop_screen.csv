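compound,ploec,log_t_half,log_kow
PAZ,7.048,1.789,1.140
Derivative-1,7.404,1.925,0.191
Derivative-2,7.575,1.954,0.140
Derivative-3,7.322,1.937,0.289
Derivative-4,6.930,1.934,1.689
Derivative-5,6.936,1.869,1.602
Derivative-6,6.777,1.926,1.254
Derivative-7,7.082,1.726,1.169
Derivative-8,7.203,1.821,1.631
Derivative-9,7.073,1.728,1.354
Derivative-10,7.089,1.744,1.113
Derivative-11,7.031,1.732,1.170
Derivative-12,7.033,1.954,1.126
Derivative-13,7.022,1.827,1.856
Derivative-14,7.009,1.555,2.623
Derivative-15,7.048,1.987,2.083
Derivative-16,7.061,1.831,1.848
Derivative-17,6.993,1.930,1.907
Derivative-18,7.007,1.862,2.102
Derivative-19,7.193,1.860,1.629
Derivative-20,7.245,1.942,2.108
Derivative-21,7.185,1.862,1.794
Derivative-22,7.129,1.952,1.768
Derivative-23,7.121,1.969,1.545
Derivative-24,7.173,1.877,1.639
Derivative-25,7.030,2.028,2.055
Derivative-26,7.034,2.073,2.254
Derivative-27,7.051,1.978,2.087
Derivative-28,7.033,1.837,1.875
Derivative-29,6.988,1.956,2.085
Derivative-30,7.055,1.847,1.917
Derivative-31,6.987,1.903,2.317
Derivative-32,6.938,1.414,2.378
Derivative-33,6.743,1.769,2.599
Derivative-34,7.253,1.438,0.486
Derivative-35,7.242,1.941,2.403
Derivative-36,7.293,1.939,2.330
Derivative-37,7.123,1.884,2.205
Derivative-38,6.949,1.709,2.515
Derivative-39,6.922,2.060,2.352
Derivative-40,6.884,1.749,2.215
Derivative-41,7.056,1.854,1.959
Derivative-42,7.076,1.942,2.184
Derivative-43,7.180,1.880,1.580
Derivative-44,7.057,1.870,1.960
Derivative-45,7.149,1.864,1.535
Derivative-46,7.155,1.953,1.614
Derivative-47,6.953,1.767,1.919
Derivative-48,7.152,1.921,1.669
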