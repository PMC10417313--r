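class,count
N,998
R,1151
T,376
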