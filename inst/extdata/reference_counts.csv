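technique,NORMAL,CARIOUS,SCLEROTIC
SW,59,31,78
SD,49,37,82
NFNBC,77,76,18
NFBC,66,84,15
FBC,59,89,20
PLMQ,24,129,
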