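biomarker,lower,upper,units
EF,48,69,%
ESP,100,174,mmHg
LFS,13,21,%
WT,18,100,%
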