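# Demonstration pipeline configuration: a small mixed two-sensor cohort
# analyzed end to end (simulate -> classify -> HMM rates -> TDP -> summary).
seed: 7
cohort:
  n_molecules: 80
  sensors: [HJ2, HJ4]
  fraction_dynamic: 0.9
  n_frames: 800
  dt: 0.1
  red_laser_start: 700
hmm:
  window_frames: 200
tdp:
  bin: 0.02
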