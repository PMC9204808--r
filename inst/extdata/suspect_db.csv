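name,formula,adducts,fragment_formulas,banned_eu,banned_spain,rfd
methylchloroisothiazolinone,C4H4ClNOS,[M+H]+,,FALSE,FALSE,
lauramide DEA,C16H33NO3,[M+H]+,C14H28NO;C4H12NO2,FALSE,FALSE,
glyceryl monostearate,C21H42O4,[M+H]+;[M+Na]+,C21H41O3;C18H37O2;C18H35O;C18H33;C12H21;C9H15;C6H13,FALSE,FALSE,
2-palmitoylglycerol,C19H38O4,[M+H]+;[M+Na]+,C19H37O3;C16H31O,FALSE,FALSE,
butyl glycol,C6H14O2,[M+H]+,C4H9O;C4H11O2,FALSE,FALSE,
aniline,C6H7N,[M+H]+,C6H6N;C5H6,FALSE,TRUE,0.007
"1,2-benzisothiazol-3(2H)-one",C7H5NOS,[M+H]+,C7H4NO;C6H6N,FALSE,FALSE,0.017
1-methylpyrrolidin-2-one,C5H9NO,[M+H]+;[M+Na]+,C4H6NO;C3H6N,TRUE,FALSE,
"N,N-dimethyldecanamide",C12H25NO,[M+H]+,C10H19O;C3H8N,FALSE,FALSE,
dipropylene glycol methyl ether,C7H16O3,[M+H]+;[M+Na]+,C4H9O2;C3H7O,FALSE,FALSE,
myreth-6,C26H54O7,[M+H]+;[M+Na]+,C14H29O;C12H25,FALSE,FALSE,
sodium dodecyl benzene sulfonate,C18H30O3S,[M-H]-,,FALSE,FALSE,0.5
sodium dodecyl sulfate,C12H26O4S,[M-H]-,,FALSE,FALSE,1
octylphenol diethoxylate,C18H30O3,[M+H]+;[M+Na]+,C8H9O;C6H5O,TRUE,FALSE,
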