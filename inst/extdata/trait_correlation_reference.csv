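trait,TN,MSN,PL,SH,PWP,GWP,SWP,TGW
TN,1,0.07,-0.13,0,0,0,0,0
MSN,0.07,1,0,0.61,0.37,0.40,0.44,0.12
PL,-0.13,0,1,0.16,0.14,0.10,0.10,0.27
SH,0,0.61,0.16,1,0.59,0.58,0.70,0.37
PWP,0,0.37,0.14,0.59,1,0.91,0.56,0.43
GWP,0,0.40,0.10,0.58,0.91,1,0.54,0.39
SWP,0,0.44,0.10,0.70,0.56,0.54,1,0.41
TGW,0,0.12,0.27,0.37,0.43,0.39,0.41,1
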