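kind: ramachandran_grid
spacing: 30.0
payload: shift_next
values:
- - 2.0
  - 1.7321
  - 1.0
  - -0.0
  - -1.0
  - -1.7321
  - -2.0
  - -1.7321
  - -1.0
  - -0.0
  - 1.0
  - 1.7321
- - 0.5
  - 0.2321
  - -0.5
  - -1.5
  - -2.5
  - -3.2321
  - -3.5
  - -3.2321
  - -2.5
  - -1.5
  - -0.5
  - 0.2321
- - -0.5981
  - -0.866
  - -1.5981
  - -2.5981
  - -3.5981
  - -4.3301
  - -4.5981
  - -4.3301
  - -3.5981
  - -2.5981
  - -1.5981
  - -0.866
- - -1.0
  - -1.2679
  - -2.0
  - -3.0
  - -4.0
  - -4.7321
  - -5.0
  - -4.7321
  - -4.0
  - -3.0
  - -2.0
  - -1.2679
- - -0.5981
  - -0.866
  - -1.5981
  - -2.5981
  - -3.5981
  - -4.3301
  - -4.5981
  - -4.3301
  - -3.5981
  - -2.5981
  - -1.5981
  - -0.866
- - 0.5
  - 0.2321
  - -0.5
  - -1.5
  - -2.5
  - -3.2321
  - -3.5
  - -3.2321
  - -2.5
  - -1.5
  - -0.5
  - 0.2321
- - 2.0
  - 1.7321
  - 1.0
  - -0.0
  - -1.0
  - -1.7321
  - -2.0
  - -1.7321
  - -1.0
  - -0.0
  - 1.0
  - 1.7321
- - 3.5
  - 3.2321
  - 2.5
  - 1.5
  - 0.5
  - -0.2321
  - -0.5
  - -0.2321
  - 0.5
  - 1.5
  - 2.5
  - 3.2321
- - 4.5981
  - 4.3301
  - 3.5981
  - 2.5981
  - 1.5981
  - 0.866
  - 0.5981
  - 0.866
  - 1.5981
  - 2.5981
  - 3.5981
  - 4.3301
- - 5.0
  - 4.7321
  - 4.0
  - 3.0
  - 2.0
  - 1.2679
  - 1.0
  - 1.2679
  - 2.0
  - 3.0
  - 4.0
  - 4.7321
- - 4.5981
  - 4.3301
  - 3.5981
  - 2.5981
  - 1.5981
  - 0.866
  - 0.5981
  - 0.866
  - 1.5981
  - 2.5981
  - 3.5981
  - 4.3301
- - 3.5
  - 3.2321
  - 2.5
  - 1.5
  - 0.5
  - -0.2321
  - -0.5
  - -0.2321
  - 0.5
  - 1.5
  - 2.5
  - 3.2321
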