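pop_a,pop_b,identity,distance
IMR,NER,0.9776,0.0227
IMR,NR,0.9590,0.0418
IMR,NWR,0.9865,0.0136
IMR,LPR,0.9636,0.0371
IMR,Abroad,0.8204,0.1980
NER,NR,0.9617,0.0391
NER,NWR,0.9901,0.0099
NER,LPR,0.9853,0.0148
NER,Abroad,0.8138,0.2060
NR,NWR,0.9781,0.0221
NR,LPR,0.9751,0.0252
NR,Abroad,0.8218,0.1963
NWR,LPR,0.9866,0.0135
NWR,Abroad,0.8123,0.2079
LPR,Abroad,0.8529,0.1591
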