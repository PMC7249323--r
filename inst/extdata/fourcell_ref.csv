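cell_id,label
c1,A
c2,A
c3,B
c4,B
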