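formula,name,rank
C16H33NO3,lauramide DEA,1
C16H33NO3,N-cocoyl diethanolamine,4
C21H42O4,glyceryl monostearate,1
C19H38O4,2-palmitoylglycerol,1
C7H5NOS,"1,2-benzisothiazol-3(2H)-one",1
C6H7N,aniline,1
C12H25NO,"N,N-dimethyldecanamide",2
C26H54O7,myreth-6,1
C24H50O5,ceteth-4,1
C26H54O6,ceteth-5,1
C28H58O7,ceteth-6,1
C30H62O8,ceteth-7,1
C32H66O9,ceteth-8,1
C34H70O10,ceteth-9,1
C36H74O11,ceteth-10,1
C38H78O12,ceteth-11,1
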