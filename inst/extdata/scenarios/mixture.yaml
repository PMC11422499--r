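# Synthetic mixed-culture scenario: a dilution-weighted blend of the two
# single-phase presets.  Additive optical components combine linearly
# with the stated weights.
components: [exponential, stationary]
weights: [0.5, 0.5]
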