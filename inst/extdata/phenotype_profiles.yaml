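sizes:
- phenotype_id: 1
  mu_l: 3.6
  sigma_l: 0.54
  mu_w: 2.232
  sigma_w: 0.3348
  texture_class: chromatin_01
- phenotype_id: 2
  mu_l: 3.9
  sigma_l: 0.585
  mu_w: 2.262
  sigma_w: 0.3393
  texture_class: chromatin_02
- phenotype_id: 3
  mu_l: 4.2
  sigma_l: 0.63
  mu_w: 2.772
  sigma_w: 0.4158
  texture_class: chromatin_03
- phenotype_id: 4
  mu_l: 4.5
  sigma_l: 0.675
  mu_w: 2.7
  sigma_w: 0.405
  texture_class: chromatin_04
- phenotype_id: 5
  mu_l: 4.8
  sigma_l: 0.72
  mu_w: 3.072
  sigma_w: 0.4608
  texture_class: chromatin_05
- phenotype_id: 6
  mu_l: 5.0
  sigma_l: 0.75
  mu_w: 2.8
  sigma_w: 0.42
  texture_class: chromatin_06
- phenotype_id: 7
  mu_l: 5.4
  sigma_l: 0.81
  mu_w: 3.888
  sigma_w: 0.5832
  texture_class: chromatin_07
- phenotype_id: 8
  mu_l: 6.0
  sigma_l: 0.9
  mu_w: 4.08
  sigma_w: 0.612
  texture_class: chromatin_08
- phenotype_id: 9
  mu_l: 6.6
  sigma_l: 0.99
  mu_w: 4.95
  sigma_w: 0.7425
  texture_class: chromatin_09
- phenotype_id: 10
  mu_l: 7.2
  sigma_l: 1.08
  mu_w: 5.04
  sigma_w: 0.756
  texture_class: chromatin_10
- phenotype_id: 11
  mu_l: 2.2
  sigma_l: 0.33
  mu_w: 1.936
  sigma_w: 0.2904
  texture_class: chromatin_11
- phenotype_id: 12
  mu_l: 2.5
  sigma_l: 0.375
  mu_w: 2.3
  sigma_w: 0.345
  texture_class: chromatin_12
- phenotype_id: 13
  mu_l: 2.8
  sigma_l: 0.42
  mu_w: 2.38
  sigma_w: 0.357
  texture_class: chromatin_13
- phenotype_id: 14
  mu_l: 3.1
  sigma_l: 0.465
  mu_w: 2.79
  sigma_w: 0.4185
  texture_class: chromatin_14
- phenotype_id: 15
  mu_l: 3.6
  sigma_l: 0.54
  mu_w: 1.512
  sigma_w: 0.2268
  texture_class: chromatin_15
- phenotype_id: 16
  mu_l: 4.0
  sigma_l: 0.6
  mu_w: 1.52
  sigma_w: 0.228
  texture_class: chromatin_16
- phenotype_id: 17
  mu_l: 4.4
  sigma_l: 0.66
  mu_w: 2.024
  sigma_w: 0.3036
  texture_class: chromatin_17
freq:
  grade_0:
    epithelial:
    - 0.1616667
    - 0.1616667
    - 0.1616667
    - 0.1616667
    - 0.1616667
    - 0.1616667
    - 0.0075
    - 0.0075
    - 0.0075
    - 0.0075
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    stromal:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0075
    - 0.0075
    - 0.0075
    - 0.0075
    - 0.1375
    - 0.1375
    - 0.1375
    - 0.1375
    - 0.14
    - 0.14
    - 0.14
  grade_1:
    epithelial:
    - 0.1166667
    - 0.1166667
    - 0.1166667
    - 0.1166667
    - 0.1166667
    - 0.1166667
    - 0.075
    - 0.075
    - 0.075
    - 0.075
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    stromal:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0375
    - 0.0375
    - 0.0375
    - 0.0375
    - 0.125
    - 0.125
    - 0.125
    - 0.125
    - 0.1166667
    - 0.1166667
    - 0.1166667
  grade_2:
    epithelial:
    - 0.0666667
    - 0.0666667
    - 0.0666667
    - 0.0666667
    - 0.0666667
    - 0.0666667
    - 0.15
    - 0.15
    - 0.15
    - 0.15
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    stromal:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.075
    - 0.075
    - 0.075
    - 0.075
    - 0.1125
    - 0.1125
    - 0.1125
    - 0.1125
    - 0.0833333
    - 0.0833333
    - 0.0833333
  grade_3:
    epithelial:
    - 0.025
    - 0.025
    - 0.025
    - 0.025
    - 0.025
    - 0.025
    - 0.2125
    - 0.2125
    - 0.2125
    - 0.2125
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    stromal:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.125
    - 0.125
    - 0.125
    - 0.125
    - 0.0875
    - 0.0875
    - 0.0875
    - 0.0875
    - 0.05
    - 0.05
    - 0.05
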