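sample	pop
DU_1	DU
DU_2	DU
DU_3	DU
DU_4	DU
DU_5	DU
DU_6	DU
DU_7	DU
DU_8	DU
MS_1	MS
MS_2	MS
MS_3	MS
BMX_1	BMX
BMX_2	BMX
BMX_3	BMX
EUW_1	EUW
EUW_2	EUW
EUW_3	EUW
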