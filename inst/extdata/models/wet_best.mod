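# Best exploratory wet-season model.  ENSO affects duration (not rainfall)
# and trend consistency; synthetic values fill the two arrows whose
# magnitudes were not printed (positive ENSO -> duration, strong negative
# ENSO -> tc).
vars nino onset duration rainfall tc
onset -> duration fixed=-0.72 source=reported
duration -> rainfall fixed=0.82 source=reported
rainfall -> tc fixed=0.75 source=reported
duration -> tc fixed=-0.60 source=reported
nino -> duration fixed=0.30 source=synthetic
nino -> tc fixed=-0.45 source=synthetic
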