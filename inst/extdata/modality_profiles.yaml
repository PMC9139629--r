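3DCRT:
  lung:
    spared:
    - 0.28
    - 0.45
    bath:
    - 0.1
    - 0.22
    high:
    - 0.04
    - 0.09
    concentration: 4.0
  breast_left:
    spared:
    - 0.15
    - 0.35
    bath:
    - 0.2
    - 0.4
    high:
    - 0.02
    - 0.06
    concentration: 4.0
  breast_right:
    spared:
    - 0.15
    - 0.35
    bath:
    - 0.2
    - 0.4
    high:
    - 0.02
    - 0.06
    concentration: 4.0
  esophagus:
    spared:
    - 0.1
    - 0.28
    bath:
    - 0.18
    - 0.35
    high:
    - 0.05
    - 0.12
    concentration: 4.0
  thyroid:
    spared:
    - 0.55
    - 1.25
    bath:
    - 0.05
    - 0.55
    high:
    - 0.0
    - 0.06
    concentration: 2.0
IMRT:
  lung:
    spared:
    - 0.18
    - 0.36
    bath:
    - 0.08
    - 0.18
    high:
    - 0.04
    - 0.09
    concentration: 4.0
  breast_left:
    spared:
    - 0.22
    - 0.42
    bath:
    - 0.14
    - 0.3
    high:
    - 0.02
    - 0.06
    concentration: 4.0
  breast_right:
    spared:
    - 0.22
    - 0.42
    bath:
    - 0.14
    - 0.3
    high:
    - 0.02
    - 0.06
    concentration: 4.0
  esophagus:
    spared:
    - 0.1
    - 0.28
    bath:
    - 0.17
    - 0.34
    high:
    - 0.05
    - 0.12
    concentration: 4.0
  thyroid:
    spared:
    - 0.55
    - 1.25
    bath:
    - 0.05
    - 0.55
    high:
    - 0.0
    - 0.06
    concentration: 2.0
PBS:
  lung:
    spared:
    - 0.58
    - 0.8
    bath:
    - 0.08
    - 0.2
    high:
    - 0.04
    - 0.09
    concentration: 4.0
  breast_left:
    spared:
    - 0.68
    - 0.9
    bath:
    - 0.05
    - 0.14
    high:
    - 0.01
    - 0.04
    concentration: 4.0
  breast_right:
    spared:
    - 0.7
    - 0.92
    bath:
    - 0.04
    - 0.12
    high:
    - 0.01
    - 0.03
    concentration: 4.0
  esophagus:
    spared:
    - 0.45
    - 0.72
    bath:
    - 0.1
    - 0.24
    high:
    - 0.03
    - 0.1
    concentration: 4.0
  thyroid:
    spared:
    - 0.55
    - 1.25
    bath:
    - 0.05
    - 0.55
    high:
    - 0.0
    - 0.06
    concentration: 2.0
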