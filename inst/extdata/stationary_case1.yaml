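name: stationary_case1
note: First stationary-frequency comparison case
regions:
- A
- B
rates:
  w:
    A: 0.01
    B: 0.02
  e:
    A: 0.169
    B: 0.008
  d:
    B>A: 0.178
    A>B: 0.002
  b:
    A|B: 0.003
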