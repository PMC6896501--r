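"block","key","value"
"incidence","40-44",15
"incidence","45-49",30
"incidence","50-54",55
"incidence","55-59",90
"incidence","60-64",150
"incidence","65-69",220
"incidence","70-74",290
"incidence","75-79",350
"incidence","80-84",400
"incidence","85-99",420
"stage","I",0.21
"stage","II",0.27
"stage","III",0.29
"stage","IV",0.23
"cum_mortality","75",0.0197
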