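# Starting wildfire model: ENSO -> dry rainfall; rainfall and previous
# wet-season trend consistency suppress fires; fire number drives area.
vars nino tc_wet rainfall n_fires area
nino -> rainfall
rainfall -> n_fires
rainfall -> area
n_fires -> area
tc_wet -> n_fires
tc_wet -> area
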