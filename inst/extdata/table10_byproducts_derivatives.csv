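parent,compound,pred59,pred61,pred_avg_printed,rel_change_printed
Derivative-1,Derivative-1,7.404,NA,NA,NA
Derivative-1,Derivative-1-Cl-1,7.335,7.907,7.621,2.93
Derivative-1,Derivative-1-Cl-2,7.439,7.745,7.592,2.54
Derivative-1,Derivative-1-Cl-3,7.523,7.615,7.569,2.23
Derivative-1,Derivative-1-Cl-4,7.162,7.466,7.314,-1.22
Derivative-1,Derivative-1-Cl-5,6.506,6.524,6.515,-12.01
Derivative-1,Derivative-1-Cl-6,6.815,7.227,7.021,-5.17
Derivative-1,Derivative-1-Cl-7,6.823,7.200,7.011,-5.31
Derivative-1,Derivative-1-Cl-8,7.125,7.181,7.153,-3.39
Derivative-1,Derivative-1-Cl-9,7.076,7.119,7.097,-4.15
Derivative-1,Derivative-1-Cl-10,7.012,7.100,7.056,-4.70
Derivative-1,Derivative-1-Cl-11,7.027,7.024,7.025,-5.12
Derivative-2,Derivative-2,7.575,NA,NA,NA
Derivative-2,Derivative-2-Cl-1,7.049,7.399,7.224,-4.63
Derivative-2,Derivative-2-Cl-2,7.145,7.293,7.219,-4.70
Derivative-2,Derivative-2-Cl-3,7.246,7.167,7.207,-4.86
Derivative-2,Derivative-2-Cl-4,6.506,6.524,6.515,-13.99
Derivative-2,Derivative-2-Cl-5,6.815,7.227,7.021,-7.31
Derivative-2,Derivative-2-Cl-6,6.823,7.200,7.011,-7.45
Derivative-2,Derivative-2-Cl-7,7.125,7.181,7.153,-5.57
Derivative-2,Derivative-2-Cl-8,7.076,7.119,7.097,-6.31
Derivative-2,Derivative-2-Cl-9,7.012,7.100,7.056,-6.85
Derivative-2,Derivative-2-Cl-10,7.027,7.024,7.025,-7.26
Derivative-3,Derivative-3,7.322,NA,NA,NA
Derivative-3,Derivative-3-Cl-1,7.396,7.951,7.674,4.81
Derivative-3,Derivative-3-Cl-2,7.493,7.811,7.652,4.51
Derivative-3,Derivative-3-Cl-3,7.578,7.683,7.630,4.21
Derivative-3,Derivative-3-Cl-4,7.162,7.466,7.314,-0.11
Derivative-3,Derivative-3-Cl-5,6.506,6.524,6.515,-11.02
Derivative-3,Derivative-3-Cl-6,6.815,7.227,7.021,-4.11
Derivative-3,Derivative-3-Cl-7,6.823,7.200,7.011,-4.25
Derivative-3,Derivative-3-Cl-8,7.125,7.181,7.153,-2.31
Derivative-3,Derivative-3-Cl-9,7.076,7.119,7.097,-3.07
Derivative-3,Derivative-3-Cl-10,7.012,7.100,7.056,-3.63
Derivative-3,Derivative-3-Cl-11,7.027,7.024,7.025,-4.06
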