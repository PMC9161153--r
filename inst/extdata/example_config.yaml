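# example configuration for the command-line tools
system:
  kind: periodic_pair_fluid
  eps: 1.0        # kJ/mol
  sigma: 2.8      # Angstrom
  cutoff: 6.5     # Angstrom
  element: X
  mass: 2.016     # amu
thermostat:
  temperature: 30    # K
  friction: 0.001    # 1/fs (1 ps^-1)
beads:
  P: 16
sampling:
  n_steps: 5000
  dt: 1.0
  stride: 10
  tolerance: 1.0     # kJ/(mol Angstrom) SEM target per record
cutoffs:
  descriptor: 4.0    # Angstrom, ML environment cutoff
model:
  L: 2
  n_radial: 11
  hidden: [8, 8]
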