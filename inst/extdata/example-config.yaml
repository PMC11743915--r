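# Example triggerbench run configuration.
# Channels mirror a common bench setup: audio triggers on the first two
# TRS contacts, a full-wave (DC-biased) input, and one de-bounced switch.
device:
  trigger_cost: 16.5
  switch_cost: 0.5
  channels:
    - kind: trigger
      front_end: half_wave
      threshold: 50
      min_pulse_duration: 10000   # µs
      pulse_increment: 0
      refractory_period: 200000
    - kind: trigger
      front_end: half_wave
      threshold: 50
      min_pulse_duration: 10000
      pulse_increment: 10000
      refractory_period: 200000
    - kind: trigger
      front_end: dc_biased
      threshold: 600
      min_pulse_duration: 10000
      pulse_increment: 0
      refractory_period: 200000
    - kind: switch
      debounce_time: 20000
      refractory_period: 100000
bench:
  n: 187
  n_channels: 8
  sampling_frequency: 6250
seed: 1
out: triggerbench-out
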