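# Saturated seasonal framework: full forward-ordered DAG over
# nino -> onset -> duration -> rainfall -> tc (df = 0).
vars nino onset duration rainfall tc
nino -> onset
nino -> duration
nino -> rainfall
nino -> tc
onset -> duration
onset -> rainfall
onset -> tc
duration -> rainfall
duration -> tc
rainfall -> tc
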