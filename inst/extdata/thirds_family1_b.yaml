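name: thirds_family1_b
note: Family-1 equal-thirds scenario, second initial condition
regions:
- A
- B
rates:
  w:
    A: 0.16
    B: 0.002
  e:
    A: 0.315
    B: 0.009
  d:
    B>A: 0.31
    A>B: 0.014
  b:
    A|B: 0.001
init:
  frequencies:
    A: 0.1
    B: 0.45
    AB: 0.45
run:
  t_max: 250.0
  n_grid: 1000.0
  epsilon: 1.0e-09
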