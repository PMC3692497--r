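(((((((Hs:148,Md:148)n7:171,Gg:319)n6:24,Xt:343)n5:75,((Ol:112,Fr:112)n9:45,Dr:157)n8:261)n4:36,((Sh:306,Ry:306)n11:115,Cm:421)n10:33)n3:93,Ci:547)n2:19,Dm:566)n1;
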