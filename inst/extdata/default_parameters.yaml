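order:
- vm1
- km1
- vm4
- km4
- vm7
- km7
- kmet
- vmsi
- kg5
- ksp
- kin7
- kout7
- k8
- kex1
- kex2
- kim1
- kim2
- vmd
ordered:
- 2.5
- 100.0
- 1.0
- 10.0
- 0.59999999999999998
- 1.0
- 6.0
- 8.0
- 0.05
- 1.0
- 4.0
- 4.0
- 18.0
- 5.40000000000000036
- 0.10000000000000001
- 4.79999999999999982
- 0.10000000000000001
- 18.0
parameters:
  vm1: 2.5
  km1: 100.0
  vm4: 1.0
  km4: 10.0
  vm7: 0.59999999999999998
  km7: 1.0
  kmet: 6.0
  vmsi: 8.0
  kg5: 0.05
  ksp: 1.0
  kin7: 4.0
  kout7: 4.0
  k8: 18.0
  kex1: 5.40000000000000036
  kex2: 0.10000000000000001
  kim1: 4.79999999999999982
  kim2: 0.10000000000000001
  vmd: 18.0
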