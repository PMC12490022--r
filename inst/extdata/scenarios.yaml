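# Example full-scale ozonation scenarios: three Swiss municipal WWTPs with
# increasing specific ozone dose. Exposures in M s; scavenger inventories in
# the units their rate constants are tabulated in (see
# scavenger_constants.csv). regime_thresholds: (lower, upper) ozone
# rate-constant bounds of the mixed abatement regime, M^-1 s^-1.
- name: Altenrhein
  specific_ozone_dose: 0.1
  o3_exposure: 1.3e-6
  oh_exposure: 2.26e-11
  oh_exposure_sd: 0.05e-11
  ph: 8.0
  o3_uncertainty_fraction: 0.8
  oh_sd_inflation: 10
  regime_thresholds: [1.0e+4, 1.0e+7]
  scavengers:
    - {species: DOM, concentration: 6.6, unit: mg_C_per_L}
    - {species: alkalinity, concentration: 4.2, unit: mmol_per_L}
    - {species: nitrite, concentration: 23.9, unit: ug_N_per_L}
    - {species: bromide, concentration: 0.06, unit: mg_per_L}
- name: Neugut
  specific_ozone_dose: 0.4
  o3_exposure: 2.2e-4
  oh_exposure: 7.76e-11
  oh_exposure_sd: 0.09e-11
  ph: 8.2
  o3_uncertainty_fraction: 0.8
  oh_sd_inflation: 10
  regime_thresholds: [1.0e+3, 1.0e+4]
  scavengers:
    - {species: DOM, concentration: 4.4, unit: mg_C_per_L}
    - {species: alkalinity, concentration: 5.3, unit: mmol_per_L}
    - {species: nitrite, concentration: 6.1, unit: ug_N_per_L}
    - {species: bromide, concentration: 0.05, unit: mg_per_L}
- name: Werdhoelzli
  specific_ozone_dose: 0.6
  o3_exposure: 2.8e-4
  oh_exposure: 2.24e-10
  oh_exposure_sd: 0.02e-10
  ph: 8.2
  o3_uncertainty_fraction: 0.8
  oh_sd_inflation: 10
  regime_thresholds: [1.0e+3, 1.0e+4]
  scavengers:
    - {species: DOM, concentration: 6.4, unit: mg_C_per_L}
    - {species: alkalinity, concentration: 3.4, unit: mmol_per_L}
    - {species: nitrite, concentration: 75.0, unit: ug_N_per_L}
    - {species: bromide, concentration: 0.05, unit: mg_per_L}
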