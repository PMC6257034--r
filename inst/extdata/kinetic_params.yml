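# Cultivar-level kinetic parameter sets for the mango softening model.
# Rates are values at the reference temperature T_ref = 295.15 K (22 degC);
# activation energies in kJ/mol. 'sd' entries are the published standard
# deviations of the estimates; Kent kfenz_ref was fixed to 1 (not estimated).
t_ref_k: 295.15
Keitt:
  kfenz_ref: 0.099
  kfenz_ref_sd: 0.007
  kd_ref: 0.219
  kd_ref_sd: 0.034
  E_fenz: 169.9
  E_fenz_sd: 3.6
  E_d: 0.01
  E_d_sd: 8.2
Kent:
  kfenz_ref: 1.0
  kfenz_ref_fixed: true
  kd_ref: 1.98
  kd_ref_sd: 0.56
  E_fenz: 194.5
  E_fenz_sd: 17.6
  E_d: 162.2
  E_d_sd: 20.3
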