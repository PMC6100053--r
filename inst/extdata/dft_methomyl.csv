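# theoretical line list (DFT, B3LYP/6-31G+(d,p)), methomyl
frequency_THz,intensity,label
1.01,1,d(C-N)ip
1.59,1,d(C-N)ip
2.01,1,d(C-N)ip + d(C-S)oop
2.68,1,d(C-H)ip
3.09,1,d(C-O)ip
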