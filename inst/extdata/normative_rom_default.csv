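age_band,movement,normative_deg
18-29,F,60
18-29,E,70
18-29,Llb,45
18-29,Rlb,45
18-29,Lrt,75
18-29,Rrt,75
30-39,F,57
30-39,E,66.5
30-39,Llb,42.75
30-39,Rlb,42.75
30-39,Lrt,71.25
30-39,Rrt,71.25
40-49,F,54
40-49,E,63
40-49,Llb,40.5
40-49,Rlb,40.5
40-49,Lrt,67.5
40-49,Rrt,67.5
50-59,F,51
50-59,E,59.5
50-59,Llb,38.25
50-59,Rlb,38.25
50-59,Lrt,63.75
50-59,Rrt,63.75
60-69,F,48
60-69,E,56
60-69,Llb,36
60-69,Rlb,36
60-69,Lrt,60
60-69,Rrt,60
70+,F,45
70+,E,52.5
70+,Llb,33.75
70+,Rlb,33.75
70+,Lrt,56.25
70+,Rrt,56.25
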