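compound	opt_e	attachment	e_tb
NH3	−35,514.577	sp3 nitrogen	−98,707.646
tert-Bu-NH2	−134,222.223		
CH4	−25,436.175	sp3 carbon	−98,711.962
tert-Bu-CH3	−124,148.137		
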