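"group","chlorophyll_a","fucoxanthin","diadinoxanthin","chlorophyll_b","lutein"
"diatoms",1,0.8,0.1,0,0
"chlorophytes",1,0,0,0.38,0.16
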