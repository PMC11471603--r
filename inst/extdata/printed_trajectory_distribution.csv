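code,label,pct
1,low-low,41.6
2,low-medium,20.5
3,low-high,5.6
4,medium-low,8.8
5,medium-medium,8.2
6,medium-high,3.6
7,high-low,1.6
8,high-medium,4.8
9,high-high,5.2
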