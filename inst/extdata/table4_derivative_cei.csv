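id,name,cei,rel_change_printed
1,1-Methyl-PAZ,0.619,-33.08
2,1-Hydrogen-PAZ,0.578,-37.51
3,1-Ethyl-PAZ,0.649,-29.84
4,1-Vinyl-PAZ,0.660,-28.65
5,1-Ethynyl-PAZ,0.719,-22.27
6,1-Carbonyl-PAZ,0.792,-14.38
7,5-Hydroxyl-PAZ,0.879,-4.97
8,5-Carboxyl-PAZ,0.827,-10.59
9,5-Sulfur-PAZ,0.848,-8.32
10,5-Fluorine-PAZ,0.814,-12.00
11,5-Chlorine-PAZ,0.717,-22.49
12,5-Bromine-PAZ,0.726,-21.51
13,1-Methyl-5-Hydroxyl-PAZ,0.762,-17.62
14,1-Methyl-5-Carboxyl-PAZ,0.743,-19.68
15,1-Methyl-5-Sulfur-PAZ,0.778,-15.89
16,1-Methyl-5-Fluorine-PAZ,0.715,-22.70
17,1-Methyl-Chlorine-PAZ,0.743,-19.68
18,1-Methyl-5-Bromine-PAZ,0.775,-16.22
19,1-Hydrogen-5-Hydroxyl-PAZ,0.652,-29.51
20,1-Hydrogen-5-Carboxyl-PAZ,0.592,-36.00
21,1-Hydrogen-5-Sulfur-PAZ,0.641,-30.70
22,1-Hydrogen-5-Fluorine-PAZ,0.549,-40.65
23,1-Hydrogen-Chlorine-PAZ,0.637,-31.14
24,1-Hydrogen-5-Bromine-PAZ,0.659,-28.76
25,1-Ethyl-5-Hydroxyl-PAZ,0.754,-18.49
26,1-Ethyl-5-Carboxyl-PAZ,0.796,-13.95
27,1-Ethyl-5-Sulfur-PAZ,0.776,-16.11
28,1-Ethyl-5-Fluorine-PAZ,0.727,-21.41
29,1-Ethyl-Chlorine-PAZ,0.828,-10.49
30,1-Ethyl-5-Bromine-PAZ,0.732,-20.86
31,1-Vinyl-5-Hydroxyl-PAZ,0.677,-26.81
32,1-Vinyl-5-Carboxyl-PAZ,0.613,-33.73
33,1-Vinyl-5-Sulfur-PAZ,0.710,-23.24
34,1-Vinyl-5-Fluorine-PAZ,0.691,-25.30
35,1-Vinyl-5-Chlorine-PAZ,0.558,-39.68
36,1-Vinyl-5-Bromine-PAZ,0.454,-50.92
37,1-Ethynyl-5-Hydroxyl-PAZ,0.659,-28.76
38,1-Ethynyl-5-Carboxyl-PAZ,0.880,-4.86
39,1-Ethynyl-5-Sulfur-PAZ,0.875,-5.41
40,1-Ethynyl-5-Fluorine-PAZ,0.742,-19.78
41,1-Ethynyl-5-Chlorine-PAZ,0.800,-13.51
42,1-Ethynyl-5-Bromine-PAZ,0.636,-31.24
43,1-Carbonyl-5-Hydroxyl-PAZ,0.718,-22.38
44,1-Carbonyl-5-Carboxyl-PAZ,0.682,-26.27
45,1-Carbonyl-5-Sulfur-PAZ,0.574,-37.95
46,1-Carbonyl-5-Fluorine-PAZ,0.600,-35.14
47,1-Carbonyl-5-Chlorine-PAZ,0.758,-18.05
48,1-Carbonyl-5-Bromine-PAZ,0.633,-31.57
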