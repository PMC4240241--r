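combination,test,gold,reaction,ppv,npv
SW x NFNBC,SW,NFNBC,NORMAL,0.83,0.74
SW x NFNBC,SW,NFNBC,CARIOUS,0.77,0.62
SW x NFNBC,SW,NFNBC,SCLEROTIC,0.13,0.94
SW x NFBC,SW,NFBC,NORMAL,0.78,0.82
SW x NFBC,SW,NFBC,CARIOUS,0.77,0.56
SW x NFBC,SW,NFBC,SCLEROTIC,0.17,0.94
SW x FBC,SW,FBC,NORMAL,0.71,0.84
SW x FBC,SW,FBC,CARIOUS,0.84,0.54
SW x FBC,SW,FBC,SCLEROTIC,0.18,0.93
SD x NFNBC,SD,NFNBC,NORMAL,0.86,0.71
SD x NFNBC,SD,NFNBC,CARIOUS,0.78,0.64
SD x NFNBC,SD,NFNBC,SCLEROTIC,0.15,0.97
SD x NFBC,SD,NFBC,NORMAL,0.84,0.79
SD x NFBC,SD,NFBC,CARIOUS,0.86,0.60
SD x NFBC,SD,NFBC,SCLEROTIC,0.18,0.97
SD x FBC,SD,FBC,NORMAL,0.76,0.82
SD x FBC,SD,FBC,CARIOUS,0.86,0.56
SD x FBC,SD,FBC,SCLEROTIC,0.20,0.95
PLMQ x NFNBC,PLMQ,NFNBC,NORMAL,0.26,0.94
PLMQ x NFNBC,PLMQ,NFNBC,CARIOUS,0.94,0.26
PLMQ x NFBC,PLMQ,NFBC,NORMAL,0.31,0.95
PLMQ x NFBC,PLMQ,NFBC,CARIOUS,0.95,0.31
PLMQ x FBC,PLMQ,FBC,NORMAL,0.33,0.95
PLMQ x FBC,PLMQ,FBC,CARIOUS,0.95,0.33
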