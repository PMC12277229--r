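authority,parameter,lower,upper,exceed_mode
WHO,ph,6.5,8.5,outside_range
USEPA,ph,6.5,8.5,outside_range
BDWS,ph,6.5,8.5,outside_range
WHO,ec,,250,above_upper
WHO,tds,600,1000,above_upper
USEPA,tds,,500,above_upper
BDWS,tds,,1000,above_upper
WHO,fe,,0.3,above_upper
USEPA,fe,,0.3,above_upper
BDWS,fe,0.3,1.0,above_upper
WHO,as,,0.01,above_upper
USEPA,as,,0.01,above_upper
BDWS,as,,0.05,above_upper
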