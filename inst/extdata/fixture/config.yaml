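seed: 101
n_flies: 6
n_repeats: 4
n_pulses:
- 1
- 5
- 10
- 20
- 30
pulse_rate: 30.0
pulse_duration: 0.002
onset_time: 5.0
sampling_rate: 10.0
duration: 16.0
fbase_floor: 0.05
cor_method: pearson
upsample: 10.0
support_fraction: 0.75
mcd_nsamp: 100
bootstrap_B: 2000
alpha: 0.01
bootstrap_scheme: holdout
holdout_frac: 0.05
protocol_select: .na
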