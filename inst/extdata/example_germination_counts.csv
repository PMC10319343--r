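"replicate","time_days","new_germinations","n_seeds"
"rep1",1,14,20
"rep1",2,3,20
"rep1",3,0,20
"rep1",4,0,20
"rep2",1,7,20
"rep2",2,8,20
"rep2",3,1,20
"rep2",4,2,20
"rep3",1,7,20
"rep3",2,6,20
"rep3",3,1,20
"rep3",4,0,20
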