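mode,dominant_left,dominant_right,ratio_dir,imbalance
normal,L3,R3,balanced,FALSE
turnaround,L3,R2,left,FALSE
scrolling,L3,R1,right,FALSE
upstairs,L1,R1,balanced,FALSE
downstairs,L2,R1,balanced,FALSE
upstairs_one_by_one,L1,R3,left,FALSE
straight_leg,L3,R2,balanced,TRUE
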