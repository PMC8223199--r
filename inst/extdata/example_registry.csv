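# Example custom adduct-registry entries for load_registry().
# Shifts are derived from the formula column at load time.
name,formula,category
waterloss,H-2O-1,custom
2x13C,[13C]2C-2,isotope
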