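# Wet-season starting model: adds the direct ENSO -> trend-consistency arrow.
vars nino onset duration rainfall tc
onset -> duration
duration -> rainfall
nino -> rainfall
rainfall -> tc
nino -> tc
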