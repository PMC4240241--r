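combination,reaction,metric,h
SW x NFNBC,NORMAL,ppv,-0.174
SW x NFNBC,NORMAL,npv,0.194
SW x NFNBC,CARIOUS,ppv,0.233
SW x NFNBC,CARIOUS,npv,-0.122
SW x NFNBC,SCLEROTIC,ppv,0.190
SW x NFNBC,SCLEROTIC,npv,0.044
SW x NFBC,NORMAL,ppv,-0.048
SW x NFBC,NORMAL,npv,0.000
SW x NFBC,CARIOUS,ppv,0.233
SW x NFBC,CARIOUS,npv,0.000
SW x NFBC,SCLEROTIC,ppv,0.077
SW x NFBC,SCLEROTIC,npv,0.044
SW x FBC,NORMAL,ppv,0.113
SW x FBC,NORMAL,npv,-0.053
SW x FBC,CARIOUS,ppv,0.056
SW x FBC,CARIOUS,npv,0.040
SW x FBC,SCLEROTIC,ppv,0.051
SW x FBC,SCLEROTIC,npv,0.085
SD x NFNBC,NORMAL,ppv,-0.257
SD x NFNBC,NORMAL,npv,0.261
SD x NFNBC,CARIOUS,ppv,0.209
SD x NFNBC,CARIOUS,npv,-0.164
SD x NFNBC,SCLEROTIC,ppv,0.132
SD x NFNBC,SCLEROTIC,npv,-0.103
SD x NFBC,NORMAL,ppv,-0.201
SD x NFBC,NORMAL,npv,0.076
SD x NFBC,CARIOUS,ppv,0.000
SD x NFBC,CARIOUS,npv,-0.081
SD x NFBC,SCLEROTIC,ppv,0.051
SD x NFBC,SCLEROTIC,npv,-0.103
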