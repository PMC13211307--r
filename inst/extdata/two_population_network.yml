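id: two-population-example
sigma:
- [1.45, 1.77]
- [0.45, 1.98]
d: [1.20, 1.80]
N0: [1.00, 1.20]
mu: [1.0, 1.0]
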