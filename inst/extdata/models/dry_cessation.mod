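# Dry-season cessation-date variant: the best dry model with cessation in
# place of onset.  source=carried values are taken over from dry_best.
vars nino cessation duration rainfall tc
cessation -> duration fixed=0.53 source=reported
duration -> rainfall fixed=0.46 source=reported
nino -> rainfall fixed=0.62 source=carried
rainfall -> tc fixed=-0.76 source=carried
duration -> tc fixed=0.53 source=carried
nino -> tc fixed=-0.25 source=synthetic
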