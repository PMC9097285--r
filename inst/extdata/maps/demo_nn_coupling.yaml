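kind: ramachandran_grid
spacing: 30.0
payload: coupling
values:
- - 0.4873
  - 0.4477
  - 0.3496
  - 0.1984
  - 0.0789
  - 0.0971
  - 0.2753
  - 0.6029
  - 1.1516
  - 1.9194
  - 2.5475
  - 2.5489
- - 0.4536
  - 0.3088
  - -0.0497
  - -0.6024
  - -1.0414
  - -0.9936
  - -0.4495
  - 0.3353
  - 1.289
  - 2.4157
  - 3.2934
  - 3.2987
- - 0.3817
  - 0.0125
  - -0.9016
  - -2.3111
  - -3.4325
  - -3.3285
  - -2.043
  - -0.4354
  - 0.994
  - 2.2662
  - 3.1528
  - 3.1665
- - 0.2895
  - -0.3673
  - -1.9933
  - -4.5009
  - -6.4971
  - -6.324
  - -4.105
  - -1.5068
  - 0.3694
  - 1.5683
  - 2.2469
  - 2.2712
- - 0.2388
  - -0.5764
  - -2.5945
  - -5.7066
  - -8.184799999999999
  - -7.9756
  - -5.253
  - -2.1496
  - -0.1304
  - 0.8638
  - 1.2892
  - 1.3193
- - 0.2738
  - -0.432
  - -2.1795
  - -4.8743
  - -7.0203
  - -6.8409
  - -4.4937
  - -1.8458
  - -0.1974
  - 0.5036
  - 0.737
  - 0.7631
- - 0.3634
  - -0.0631
  - -1.1187
  - -2.7467
  - -4.0431
  - -3.9352
  - -2.5195
  - -0.9287
  - 0.0445
  - 0.4319
  - 0.5424
  - 0.5582
- - 0.4424
  - 0.2627
  - -0.1822
  - -0.8684
  - -1.4148
  - -1.3694
  - -0.7731
  - -0.104
  - 0.3026
  - 0.4602
  - 0.502
  - 0.5086
- - 0.4831
  - 0.4302
  - 0.2994
  - 0.0976
  - -0.0631
  - -0.0497
  - 0.1256
  - 0.3222
  - 0.4414
  - 0.4871
  - 0.4988
  - 0.5008
- - 0.4965
  - 0.4857
  - 0.4588
  - 0.4175
  - 0.3845
  - 0.3872
  - 0.4232
  - 0.4635
  - 0.4879
  - 0.4973
  - 0.4996
  - 0.5
- - 0.4995
  - 0.498
  - 0.4941
  - 0.4882
  - 0.4835
  - 0.4839
  - 0.489
  - 0.4948
  - 0.4983
  - 0.4996
  - 0.4999
  - 0.5
- - 0.5
  - 0.4998
  - 0.4994
  - 0.4988
  - 0.4983
  - 0.4984
  - 0.4989
  - 0.4995
  - 0.4998
  - 0.5
  - 0.5
  - 0.5
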