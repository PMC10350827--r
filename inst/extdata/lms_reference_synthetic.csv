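"sex","age_weeks","L","M","S"
"female",30,1,1.3,0.15
"female",32,1,1.581,0.15
"female",34,1,1.862,0.15
"female",36,1,2.144,0.15
"female",38,1,2.425,0.15
"female",40,1,2.706,0.15
"female",42,1,2.987,0.15
"female",44,1,3.269,0.15
"female",46,1,3.55,0.15
"male",30,1,1.35,0.15
"male",32,1,1.644,0.15
"male",34,1,1.938,0.15
"male",36,1,2.231,0.15
"male",38,1,2.525,0.15
"male",40,1,2.819,0.15
"male",42,1,3.113,0.15
"male",44,1,3.406,0.15
"male",46,1,3.7,0.15
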