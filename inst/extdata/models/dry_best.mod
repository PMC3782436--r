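# Best exploratory dry-season model.  Standardized coefficients:
# source=reported are the published estimates for the 58-year record;
# source=synthetic are implementer defaults for simulation only (the
# ENSO -> tc arrow was reported as weak, negative and significant, without
# a printed value).
vars nino onset duration rainfall tc
onset -> duration fixed=-0.69 source=reported
duration -> rainfall fixed=0.46 source=reported
nino -> rainfall fixed=0.62 source=reported
rainfall -> tc fixed=-0.76 source=reported
duration -> tc fixed=0.53 source=reported
nino -> tc fixed=-0.25 source=synthetic
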