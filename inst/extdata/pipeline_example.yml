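# Example gaitpress pipeline configuration (flat key: value format).
# The seed is mandatory whenever a simulation section is present.
simulation.modes: normal,scrolling,straight_leg
simulation.repeats: 3
simulation.n_steps: 6
simulation.cadence: 1
simulation.sampling_rate: 100
simulation.noise_sd: 0.05
simulation.drift: 0
simulation.seed: 42
extraction.high_frac: 0.2
extraction.low_frac: 0.1
extraction.min_width: 0.1
stats.alpha: 0.95
paths.outdir: gaitpress_run
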