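running late
walk away
walking dead
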