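stage,count
I,44
II,173
III,168
IV,41
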