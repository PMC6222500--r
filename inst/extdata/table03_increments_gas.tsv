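compound	opt_e	attachment	e_tb
NH3	−35,508.975	sp3 nitrogen	−98,709.131
tert-Bu-NH2	−134,218.106		
CH4	−25,437.531	sp3 carbon	−98,712.134
tert-Bu-CH3	−124,149.665		
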