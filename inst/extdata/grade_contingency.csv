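"","normal","indeterminate","grade1","grade2","grade3"
"normal",15,4,1,0,0
"indeterminate",0,1,1,1,1
"grade1",0,0,1,0,0
"grade2",0,0,0,2,0
"grade3",0,0,0,0,1
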