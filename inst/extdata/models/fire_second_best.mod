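# Second-best wildfire model (preferred for its simplicity and explanatory
# power): all five standardized coefficients were printed.
vars nino tc_wet rainfall n_fires area
nino -> rainfall fixed=0.59 source=reported
tc_wet -> rainfall fixed=0.35 source=reported
rainfall -> area fixed=-0.51 source=reported
n_fires -> area fixed=0.51 source=reported
tc_wet -> n_fires fixed=-0.52 source=reported
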