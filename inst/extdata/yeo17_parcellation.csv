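network,group
Visual A,Storage
Visual B,Storage
Somatomotor A,Storage
Somatomotor B,Storage
Dorsal Attention A,Retrieval
Dorsal Attention B,Storage
Salience A,Storage
Salience B,Retrieval
Limbic A,Storage
Limbic B,Retrieval
Control A,Retrieval
Control B,Retrieval
Control C,Storage
Default A,DMN
Default B,DMN
Default C,DMN
Temporal Parietal,Retrieval
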