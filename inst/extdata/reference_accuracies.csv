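technique,reaction,accuracy
SW,NORMAL,0.7976
SW,CARIOUS,0.5952
SW,SCLEROTIC,0.5833
SD,NORMAL,0.7976
SD,CARIOUS,0.631
SD,SCLEROTIC,0.5833
PLMQ,NORMAL,0.7902
PLMQ,CARIOUS,0.7092
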