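label,events_a,n_a,events_b,n_b
near_miss,30,18762,9,18767
error,5,18762,1,18767
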