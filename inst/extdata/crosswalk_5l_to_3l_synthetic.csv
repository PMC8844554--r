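dimension,from_level,to_level
all,1,1
all,2,2
all,3,2
all,4,3
all,5,3
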