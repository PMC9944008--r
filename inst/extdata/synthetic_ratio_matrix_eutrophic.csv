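"group","chlorophyll_a","fucoxanthin","diadinoxanthin","chlorophyll_b","lutein"
"diatoms",1,0.7,0.14,0,0
"chlorophytes",1,0,0,0.33,0.2
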