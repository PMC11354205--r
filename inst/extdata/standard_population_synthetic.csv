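bin_label,weight
50-54,0.215
55-59,0.200
60-64,0.180
65-69,0.150
70-74,0.110
75-79,0.075
80-84,0.045
85+,0.025
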