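names:
  eta1:
  - Att
  - Strat
  - Math
  eta2:
  - Prob
  - Soc
  - AlphaMath
  'y':
  - y1
  - y2
  - y3
  - y4
  - y5
  - y6
  - y7
  - y8
  - y9
  z:
  - z1
  - z2
  - z3
  - z4
  - z5
  - z6
level1:
  f:
  - Att
  - Strat
  - Math
  F:
  - Att
  - Att^2
  - Att^3
  - tp(Att, knot=2, degree=3)
  - tp(Att, knot=3, degree=3)
  - Strat
  - Strat^2
  - Strat^3
  - tp(Strat, knot=2, degree=3)
  - tp(Strat, knot=3, degree=3)
  nu:
    values:
    - 0.0
    - -1.078
    - -0.409
    - 0.0
    - 0.411
    - -0.419
    - 0.0
    - 0.058
    - 0.34
    free:
    - no
    - yes
    - yes
    - no
    - yes
    - yes
    - no
    - yes
    - yes
  lambda:
    values:
    - - 1.0
      - 0.0
      - 0.0
    - - 1.141
      - 0.0
      - 0.0
    - - 0.997
      - 0.0
      - 0.0
    - - 0.0
      - 1.0
      - 0.0
    - - 0.0
      - 0.687
      - 0.0
    - - 0.0
      - 1.213
      - 0.0
    - - 0.0
      - 0.0
      - 1.0
    - - 0.0
      - 0.0
      - 0.754
    - - 0.0
      - 0.0
      - 0.553
    free:
    - - no
      - no
      - no
    - - yes
      - no
      - no
    - - yes
      - no
      - no
    - - no
      - no
      - no
    - - no
      - yes
      - no
    - - no
      - yes
      - no
    - - no
      - no
      - no
    - - no
      - no
      - yes
    - - no
      - no
      - yes
  theta:
    dim: 9
    blocks:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
    - 8
    - 9
    values:
    - 0.147
    - 0.198
    - 0.212
    - 0.212
    - 0.323
    - 0.219
    - 0.066
    - 0.047
    - 0.049
    free:
    - yes
    - yes
    - yes
    - yes
    - yes
    - yes
    - yes
    - yes
    - yes
  alpha:
    values:
    - 2.856
    - 2.7
    - 0.0
    free:
    - yes
    - yes
    - no
  B:
    values:
    - - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
    - - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
    - - 0.005
      - 0.009
      - -0.005
      - 0.046
      - -0.164
      - -0.07
      - 0.079
      - -0.017
      - 0.007
      - 0.018
    free:
    - - no
      - no
      - no
      - no
      - no
      - no
      - no
      - no
      - no
      - no
    - - no
      - no
      - no
      - no
      - no
      - no
      - no
      - no
      - no
      - no
    - - yes
      - yes
      - yes
      - yes
      - yes
      - yes
      - yes
      - yes
      - yes
      - yes
  psi:
    dim: 3
    blocks:
    - - 1
      - 2
    - 3
    values:
    - - - 0.506
        - 0.072
      - - 0.072
        - 0.25
    - 0.041
    free:
    - yes
    - yes
  mixture:
    classes: 1
level2:
  f:
  - Prob
  - Soc
  F:
  - Prob
  - Soc
  - Prob*Soc
  nu:
    values:
    - 0.0
    - 0.759
    - 0.603
    - 0.0
    - -0.024
    - 0.279
    free:
    - no
    - yes
    - yes
    - no
    - yes
    - yes
  lambda:
    values:
    - - 1.0
      - 0.0
    - - 1.029
      - 0.0
    - - 0.7
      - 0.0
    - - 0.0
      - 1.0
    - - 0.0
      - 1.002
    - - 0.0
      - 0.794
    free:
    - - no
      - no
    - - yes
      - no
    - - yes
      - no
    - - no
      - no
    - - no
      - yes
    - - no
      - yes
  theta:
    dim: 6
    blocks:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    values:
    - 0.415
    - 0.723
    - 0.366
    - 0.183
    - 0.13
    - 0.176
    free:
    - yes
    - yes
    - yes
    - yes
    - yes
    - yes
  alpha:
    values:
    - - 1.921
      - 1.938
      - -0.365
    - - 2.107
      - 2.091
      - -0.365
    free:
    - yes
    - yes
    - yes
    vary: d
    vary_rows:
    - 1
    - 2
  B:
    values:
    - - 0.0
      - 0.0
      - 0.0
    - - 0.0
      - 0.0
      - 0.0
    - - 0.558
      - 0.442
      - -0.289
    free:
    - - no
      - no
      - no
    - - no
      - no
      - no
    - - yes
      - yes
      - yes
  psi:
    dim: 3
    blocks:
    - - 1
      - 2
    - 3
    values:
    - - - 0.291
        - 0.007
      - - 0.007
        - 0.239
    - 0.051
    free:
    - yes
    - yes
  mixture:
    classes: 2
    a:
    - 0.0
    - -0.128175193424
    h: ~
random:
- block: alpha
  row: 3
  col: 1
  eta2: 3
links:
  'y':
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  z:
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
  - link: identity
ordered_block:
  level: 2.0
  block: alpha
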