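# Example configuration: every key mirrors the parameter containers
# field for field; unspecified keys keep the package defaults.
lp:
  gamma: 0.01
  kick_speed: 1.0
  kick_rate: 0.002
  hydrophobic_multiplier: 3
  exposure_rays: 32
  exposure_every: 4
ff:
  k_cov: 1.0
  k_bb: 0.3
  hb_strength: 0.25
scene:
  container_radius: 50
  ribosome_radius: 100
  crowder_radius: 15
  crowder_mass: 150
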