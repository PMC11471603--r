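gender,age,label,total_le,robust_le,frailty_le,prop_robust,prop_frailty
male,65,low,14.34,4.74,9.59,33.05,66.95
male,65,medium,14.47,5.07,9.40,35.04,64.96
male,65,high,14.62,5.44,9.19,37.21,62.79
male,75,low,9.62,3.03,6.59,31.50,68.50
male,75,medium,9.74,3.29,6.45,33.78,66.22
male,75,high,9.91,3.61,6.30,36.43,63.57
female,65,low,15.50,4.15,11.35,26.77,73.23
female,65,medium,15.56,4.45,11.11,28.60,71.40
female,65,high,15.65,4.79,10.86,30.61,69.39
female,75,low,10.55,2.69,7.86,25.50,74.50
female,75,medium,10.65,2.96,7.69,27.79,72.21
female,75,high,10.73,3.21,7.52,29.92,70.08
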