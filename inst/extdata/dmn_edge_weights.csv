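network_a,network_b,beta
Default A,Default C,0.055810
Default A,Limbic A,-0.014422
Default B,Control C,-0.022168
Default B,Salience A,0.025213
Default B,Visual A,0.058361
Default C,Dorsal Attention B,-0.027954
Default C,Limbic A,0.017076
Default C,Somatomotor A,0.008430
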