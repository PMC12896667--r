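predicted,Standing,Lying Down,Foraging/Feeding,Locomotion,Out of View/Not Labeled
Standing,100,2,158,27,0
Lying Down,9,225,3,0,0
Foraging/Feeding,1,0,221,2,0
Locomotion,0,0,0,26,0
Out of View/Not Labeled,85,41,11,3,286
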