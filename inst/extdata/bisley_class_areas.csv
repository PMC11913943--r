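class,y2009,y2014,y2019,y2023,y2028,y2033
woody,133.32,181.05,224.55,261.86,281.31,304.91
grasses,213.15,153.79,124.93,89.79,66.89,46.10
bare,7.28,18.96,4.28,2.00,5.55,2.75
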