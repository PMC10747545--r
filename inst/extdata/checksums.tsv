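file	md5
table1.tsv	3e3eb54ca1f4d9120106dd4ceede4d75
table3.tsv	fa6f692cbf011c02384c7f8bbaa3a102
table4.tsv	cb343a1ce11be6914449073d461e4f2d
table5.tsv	8fa9658a9ac1dee9aeb03281f66396c7
table6.tsv	f132785cbd18ba71842fe3552c4fd239
medians.tsv	5462d94a68c6ae123346d2e437aa4f76
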