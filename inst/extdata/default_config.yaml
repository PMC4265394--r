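er_pos:
  hr_node: 1.75
  hr_size: 1.43
  hr_grade: 2.33
  hr_screen: 0.7
  baseline_annual_hazard:
  - 0.0015
  - 0.0025
  - 0.0035
  - 0.004
  - 0.0042
  - 0.0042
  - 0.004
  - 0.0038
  - 0.0036
  - 0.0034
er_neg:
  hr_node: 1.55
  hr_size: 1.44
  hr_grade: 1.5
  hr_screen: 0.86
  baseline_annual_hazard:
  - 0.02
  - 0.022
  - 0.019
  - 0.015
  - 0.011
  - 0.008
  - 0.007
  - 0.005
  - 0.004
  - 0.004
ki67:
  hr: 1.3
  prevalence: 0.412
her2:
  hr: 1.8
  prevalence: 0.089
life_table:
  age:
  - 25
  - 26
  - 27
  - 28
  - 29
  - 30
  - 31
  - 32
  - 33
  - 34
  - 35
  - 36
  - 37
  - 38
  - 39
  - 40
  - 41
  - 42
  - 43
  - 44
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  annual_hazard:
  - 0.0003112
  - 0.0003388
  - 0.0003689
  - 0.0004016
  - 0.0004373
  - 0.000476
  - 0.0005183
  - 0.0005643
  - 0.0006143
  - 0.0006688
  - 0.0007282
  - 0.0007928
  - 0.0008631
  - 0.0009397
  - 0.001023
  - 0.0011138
  - 0.0012126
  - 0.0013202
  - 0.0014373
  - 0.0015648
  - 0.0017036
  - 0.0018548
  - 0.0020193
  - 0.0021985
  - 0.0023935
  - 0.0026058
  - 0.002837
  - 0.0030887
  - 0.0033627
  - 0.0036611
  - 0.0039859
  - 0.0043395
  - 0.0047245
  - 0.0051436
  - 0.0055999
  - 0.0060967
  - 0.0066376
  - 0.0072265
  - 0.0078676
  - 0.0085656
  - 0.0093255
  - 0.0101529
  - 0.0110536
  - 0.0120342
  - 0.0131019
  - 0.0142642
  - 0.0155297
  - 0.0169075
  - 0.0184074
  - 0.0200405
  - 0.0218184
  - 0.0237541
  - 0.0258615
  - 0.0281559
  - 0.0306538
  - 0.0333733
  - 0.036334
  - 0.0395575
  - 0.0430669
  - 0.0468877
  - 0.0510474
  - 0.0555762
  - 0.0605068
  - 0.0658748
  - 0.071719
  - 0.0780817
  - 0.0850088
  - 0.0925506
  - 0.1007614
  - 0.1097006
  - 0.119433
  - 0.1300287
  - 0.1415645
  - 0.1541237
  - 0.1677971
  - 0.1826835
treatment:
  endocrine: 0.7
  chemo: 0.78
horizon_years: 10.0
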