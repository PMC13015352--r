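# Stress-rule demonstration: threshold 15 gives a deterministic adult size
# of 33 cells (the closest odd size to the target 32) and zero variance.
rule: stress
theta: 15
n_events: 100
events_per_run: 100
target_size: 32
seed: 1
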