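{"labels":["HT1197","HT1197","HT1197","RT112","RT112","RT112"],"meta":[{"id":"s0001","t_acq":10,"cr":0.996931249055334,"cb":0.752283629564556,"cosmic_channels":[62,103,252,253,254]},{"id":"s0002","t_acq":10,"cr":1.11611901125816,"cb":1.07955169808478,"cosmic_channels":[58,59,69,70]},{"id":"s0003","t_acq":10,"cr":1.11909956566689,"cb":0.845301893429274,"cosmic_channels":[49,50,149,150]},{"id":"s0004","t_acq":10,"cr":0.832269294665539,"cb":0.76996065193448,"cosmic_channels":[145,146,165,166,167,237,238,239]},{"id":"s0005","t_acq":10,"cr":0.833025263394373,"cb":1.02001940723596,"cosmic_channels":[62,63,196,197,198]},{"id":"s0006","t_acq":10,"cr":0.783285817939918,"cb":0.814772101280358,"cosmic_channels":[134,135,136,250,251,252]}]}
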