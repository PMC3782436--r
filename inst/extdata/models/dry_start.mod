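# Dry-season starting model: theory-based arrows only.
vars nino onset duration rainfall tc
onset -> duration
duration -> rainfall
nino -> rainfall
rainfall -> tc
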