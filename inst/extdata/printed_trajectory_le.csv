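gender,age,code,label,total_le,robust_le,frailty_le,prop_robust,prop_frailty
male,65,1,low-low,14.097,4.465,9.633,31.67,68.33
male,65,2,low-medium,14.155,4.538,9.617,32.06,67.94
male,65,3,low-high,14.216,4.615,9.601,32.46,67.54
male,65,4,medium-low,14.274,4.671,9.602,32.72,67.28
male,65,5,medium-medium,14.332,4.747,9.585,33.12,66.88
male,65,6,medium-high,14.368,4.803,9.565,33.43,66.57
male,65,7,high-low,14.434,4.892,9.542,33.89,66.11
male,65,8,high-medium,14.525,5.000,9.524,34.42,65.58
male,65,9,high-high,14.575,5.080,9.495,34.85,65.15
male,75,1,low-low,9.49,2.91,6.58,30.66,69.34
male,75,2,low-medium,9.57,3.01,6.56,31.45,68.55
male,75,3,low-high,9.65,3.11,6.53,32.23,67.77
male,75,4,medium-low,9.72,3.20,6.52,32.92,67.08
male,75,5,medium-medium,9.79,3.30,6.49,33.71,66.29
male,75,6,medium-high,9.87,3.41,6.46,34.55,65.45
male,75,7,high-low,9.96,3.52,6.44,35.34,64.66
male,75,8,high-medium,10.04,3.63,6.41,36.16,63.84
male,75,9,high-high,10.13,3.75,6.38,37.02,62.98
female,65,1,low-low,15.313,3.950,11.363,25.80,74.20
female,65,2,low-medium,15.341,4.013,11.328,26.16,73.84
female,65,3,low-high,15.387,4.072,11.315,26.46,73.54
female,65,4,medium-low,15.434,4.131,11.303,26.77,73.23
female,65,5,medium-medium,15.485,4.193,11.292,27.08,72.92
female,65,6,medium-high,15.533,4.257,11.276,27.41,72.59
female,65,7,high-low,15.579,4.323,11.256,27.75,72.25
female,65,8,high-medium,15.635,4.395,11.241,28.11,71.89
female,65,9,high-high,15.694,4.471,11.223,28.49,71.51
female,75,1,low-low,10.47,2.64,7.83,25.21,74.79
female,75,2,low-medium,10.52,2.72,7.80,25.86,74.14
female,75,3,low-high,10.59,2.82,7.77,26.63,73.37
female,75,4,medium-low,10.66,2.91,7.75,27.30,72.70
female,75,5,medium-medium,10.73,3.00,7.72,27.96,72.04
female,75,6,medium-high,10.80,3.10,7.69,28.70,71.30
female,75,7,high-low,10.86,3.20,7.66,29.47,70.53
female,75,8,high-medium,10.94,3.30,7.64,30.16,69.84
female,75,9,high-high,11.02,3.41,7.61,30.94,69.06
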