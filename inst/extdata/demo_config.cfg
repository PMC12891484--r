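# demo configuration for `oscphen::cli()` run-all
sampling_rate=400
duration=30
n_subjects=2
n_boot=200
aperiodic.b=2
aperiodic.m=-2
aperiodic.knee=4
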