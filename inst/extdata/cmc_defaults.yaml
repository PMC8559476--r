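# Canonical-microcircuit base values (version 1).
#
# Four populations per source -- spiny stellate (ss), superficial pyramidal
# (sp), inhibitory interneurons (ii), deep pyramidal (dp) -- each with
# second-order (current/voltage) kinetics.  Free parameters are log-scalings
# of the signed base couplings below, so effective strengths are always
# positive multiples of these fixed-sign bases.
version: 1
populations: [ss, sp, ii, dp]
# membrane time constants per population (seconds)
tau: {ss: 0.004, sp: 0.008, ii: 0.016, dp: 0.020}
# baseline-subtracted sigmoid: rate = max * (logistic(slope * v) - 1/2)
sigmoid:
  slope: 0.6667   # 1/mV
  max: 1.0        # normalised peak rate
# intrinsic couplings, "<source>_<target>": signed gains on presynaptic
# firing rates; negative entries are inhibitory.  sp_sp is the superficial
# pyramidal self-inhibition ("gain") whose log-scaling is the modulable
# intrinsic parameter.
intrinsic:
  ss_ss: -800
  sp_ss: -400
  ii_ss: -800
  ii_ii: -400
  ss_ii: 400
  dp_ii: 200
  sp_sp: -400
  ss_sp: 400
  ii_dp: -200
  dp_dp: -100
# extrinsic base strengths: forward connections arise from superficial
# pyramidal cells and excite spiny stellate and deep pyramidal targets;
# backward connections arise from deep pyramidal cells and inhibit
# superficial pyramidal and inhibitory interneuron targets.
extrinsic:
  forward: {ss: 1600, dp: 800}
  backward: {sp: -800, ii: -400}
# conduction delays (ms), implemented on the integration grid
delays: {intrinsic: 1.0, extrinsic: 8.0}
# thalamic input: Gaussian bump peaking 60 ms after sound onset
input: {peak_s: 0.060, width_s: 0.016, amplitude: 100.0}
# integration
integration: {step_s: 0.001, divergence_bound: 1000000.0}
# observation model defaults
observation:
  n_modes: 8
  head_radius_m: 0.09
  sensor_radius_m: 0.102
  sphere_center_m: [0.0, 0.0, 0.02]
  dipole_moment_nAm: 20
  location_prior_sd_m: 0.008
# study-condition defaults for synthetic cohorts
study:
  n_per_group: 20
  conditions: [HP, LP]
  snr: 5
  random_effects_sd: 0.15
  effect_size: 0.5
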