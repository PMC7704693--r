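# Digital dynamic head phantom study: the seven-condition experiment.
#
# Schema:
#   phantom      preset name (currently "forbild-head")
#   seed         integer RNG seed; all Poisson noise derives from it
#   n_emitted    full-dose emitted photons per detector per view (N_e)
#   kernel       Kaiser-Bessel regridding parameters
#   doses        list of dose levels; each has
#     fraction      tube-current fraction in (0, 1]
#     ring_presets  KWIA ring presets applied at that dose (optional)
phantom: forbild-head
seed: 1
n_emitted: 4.8e6
kernel:
  kb_beta: 16.25
  width: 7
  oversampling: 2
doses:
  - fraction: 1.0
  - fraction: 0.5
    ring_presets: [kwia50-2ring, kwia50-3ring]
  - fraction: 0.25
    ring_presets: [kwia25-3ring, kwia25-4ring]
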