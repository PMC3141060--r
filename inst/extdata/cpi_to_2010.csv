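year,factor_to_2010
1999,1.309
2000,1.266
2001,1.231
2002,1.212
2003,1.185
2004,1.154
2005,1.117
2006,1.082
2007,1.052
2008,1.013
2009,1.016
2010,1.000
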