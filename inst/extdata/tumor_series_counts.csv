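variable,level,count
Histological grade,1,75
Histological grade,2,117
Histological grade,3,204
Histological grade,Missing,20
ERalpha,Negative,140
ERalpha,Positive,274
ERalpha,Missing,2
HER2,Negative,352
HER2,Positive,60
HER2,Missing,4
EGFR,Negative,395
EGFR,Positive,21
EGFR,Missing,0
CK5,Negative,357
CK5,Positive,59
CK5,Missing,0
CK14,Negative,394
CK14,Positive,22
CK14,Missing,0
Vimentin,Negative,345
Vimentin,Positive,69
Vimentin,Missing,2
CD44,Negative,205
CD44,Positive,210
CD44,Missing,1
Subtype,Luminal,303
Subtype,Her2,29
Subtype,Triple-Negative,84
Subtype,Missing,0
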