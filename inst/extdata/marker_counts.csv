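marker,n_marked,N_total,daughters_marked
mAb62_N-FCR,22,515,1
eYFP-FCP3_O-FCR,7,515,1
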