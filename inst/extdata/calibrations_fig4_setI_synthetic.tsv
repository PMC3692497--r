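clade_tips	lower_Ma	upper_Ma	style
Hs,Dm	550	581	soft
Hs,Ci	NA	581	soft
Hs,Cm	422	463	soft
Hs,Dr	416	422	soft
Hs,Xt	330	350	soft
Hs,Gg	312	330	soft
Hs,Md	125	171	soft
Ol,Dr	150	165	soft
Ol,Fr	97	151	soft
Cm,Sh	410	NA	hard-lower
Sh,Ry	250	NA	hard-lower
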