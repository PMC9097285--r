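kind: ramachandran_grid
spacing: 30.0
payload: shift_prev
values:
- - -4.0
  - -5.0
  - -5.7321
  - -6.0
  - -5.7321
  - -5.0
  - -4.0
  - -3.0
  - -2.2679
  - -2.0
  - -2.2679
  - -3.0
- - -3.4641
  - -4.4641
  - -5.1962
  - -5.4641
  - -5.1962
  - -4.4641
  - -3.4641
  - -2.4641
  - -1.7321
  - -1.4641
  - -1.7321
  - -2.4641
- - -2.0
  - -3.0
  - -3.7321
  - -4.0
  - -3.7321
  - -3.0
  - -2.0
  - -1.0
  - -0.2679
  - 0.0
  - -0.2679
  - -1.0
- - 0.0
  - -1.0
  - -1.7321
  - -2.0
  - -1.7321
  - -1.0
  - 0.0
  - 1.0
  - 1.7321
  - 2.0
  - 1.7321
  - 1.0
- - 2.0
  - 1.0
  - 0.2679
  - 0.0
  - 0.2679
  - 1.0
  - 2.0
  - 3.0
  - 3.7321
  - 4.0
  - 3.7321
  - 3.0
- - 3.4641
  - 2.4641
  - 1.7321
  - 1.4641
  - 1.7321
  - 2.4641
  - 3.4641
  - 4.4641
  - 5.1962
  - 5.4641
  - 5.1962
  - 4.4641
- - 4.0
  - 3.0
  - 2.2679
  - 2.0
  - 2.2679
  - 3.0
  - 4.0
  - 5.0
  - 5.7321
  - 6.0
  - 5.7321
  - 5.0
- - 3.4641
  - 2.4641
  - 1.7321
  - 1.4641
  - 1.7321
  - 2.4641
  - 3.4641
  - 4.4641
  - 5.1962
  - 5.4641
  - 5.1962
  - 4.4641
- - 2.0
  - 1.0
  - 0.2679
  - 0.0
  - 0.2679
  - 1.0
  - 2.0
  - 3.0
  - 3.7321
  - 4.0
  - 3.7321
  - 3.0
- - 0.0
  - -1.0
  - -1.7321
  - -2.0
  - -1.7321
  - -1.0
  - 0.0
  - 1.0
  - 1.7321
  - 2.0
  - 1.7321
  - 1.0
- - -2.0
  - -3.0
  - -3.7321
  - -4.0
  - -3.7321
  - -3.0
  - -2.0
  - -1.0
  - -0.2679
  - 0.0
  - -0.2679
  - -1.0
- - -3.4641
  - -4.4641
  - -5.1962
  - -5.4641
  - -5.1962
  - -4.4641
  - -3.4641
  - -2.4641
  - -1.7321
  - -1.4641
  - -1.7321
  - -2.4641
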