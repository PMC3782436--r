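# Saturated wildfire framework (starting model plus the saturating arrows
# and the exogenous covariance; df = 0).
vars nino tc_wet rainfall n_fires area
nino -> rainfall
rainfall -> n_fires
rainfall -> area
n_fires -> area
tc_wet -> n_fires
tc_wet -> area
nino -> n_fires
nino -> area
tc_wet -> rainfall
cov nino ~~ tc_wet
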