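cell_id,label
c1,1
c2,2
c3,1
c4,2
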