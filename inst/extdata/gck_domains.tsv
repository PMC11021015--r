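domain	start	end
large	1	64
small	72	201
large	206	439
small	447	461
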