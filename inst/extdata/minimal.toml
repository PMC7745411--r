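# minimal run configuration: everything except the carrying capacity
# (the largest population the culture reaches if left alone) has a default
carrying_capacity = 3e6  # cells
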