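# SYNTHETIC example correlation coefficients -- illustrative values for
# testing the parameter-file machinery only, NOT calibrated literature
# coefficients. For real predictions substitute a file with the published
# ozone QSAR correlations (Lee, Kamath & von Gunten lineage) on the
# matching sigma scales.
correlations:
  - family: phenol
    intercept: 3.0
    slope: -2.0
    scale: hammett_sigma_plus
    note: synthetic example
  - family: phenolate
    intercept: 9.0
    slope: -2.5
    scale: hammett_sigma_minus
    note: synthetic example
  - family: amine
    intercept: 5.5
    slope: -1.5
    scale: taft_sigma_star
    note: synthetic example
  - family: olefin
    intercept: 5.0
    slope: -1.0
    scale: taft_sigma_star
    note: synthetic example
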