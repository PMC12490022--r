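species,basis,k,source
DOM,per_mg_C,2.5e4,"Westerhoff et al. 1999, Water Res. 33:2265 (L mgC-1 s-1)"
bicarbonate,per_M,8.5e6,"Buxton et al. 1988, J. Phys. Chem. Ref. Data 17:513"
carbonate,per_M,3.9e8,"Buxton et al. 1988, J. Phys. Chem. Ref. Data 17:513"
nitrite,per_M,1.0e10,"Buxton et al. 1988, J. Phys. Chem. Ref. Data 17:513"
bromide,per_M,1.1e10,"Buxton et al. 1988, J. Phys. Chem. Ref. Data 17:513"
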