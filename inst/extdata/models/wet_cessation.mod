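# Wet-season cessation-date variant: ENSO delays cessation (0.35), which
# lengthens the season (0.76) and adds rainfall via duration (0.82).
vars nino cessation duration rainfall tc
nino -> cessation fixed=0.35 source=reported
cessation -> duration fixed=0.76 source=reported
duration -> rainfall fixed=0.82 source=reported
rainfall -> tc fixed=0.75 source=carried
duration -> tc fixed=-0.60 source=carried
nino -> tc fixed=-0.45 source=synthetic
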