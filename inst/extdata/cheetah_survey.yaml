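# Pinned survey scenario: structure of an intensive three-month
# search-encounter carnivore survey (92 daily occasions, five vehicles,
# ~8,400 km of patchy effort, ~43% unsuitable habitat, female-biased
# population with sex-specific movement scales). Tuning constants are
# versioned here, not hard-coded.
extent_km: 28
buffer_km: 16
ss_side_km: 0.65
trap_side_km: 1
frac_unsuitable: 0.4258
habitat_seeds: 8
n_animals: 130
psi_sex: 0.162
lam0: 0.004
beta_eff: -0.009
beta_sex: -0.12
sigma_F: 3.0
sigma_M: 8.0
theta: 0.83
K: 92
searchers: 5
daily_km: 18.26
fix_spacing_km: 0.1
hotspot: true
hotspot_sd_km: 10
patrol_radius_km: 13
turn_sd: 0.4
start_date: '2014-08-01'
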