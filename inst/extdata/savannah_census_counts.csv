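area_id,pilot,reference,classified,correct
A1,A,76,90,74
A2,A,155,166,140
A3,A,72,78,69
B1,B,40,41,38
B2,B,53,55,49
B3,B,57,60,53
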