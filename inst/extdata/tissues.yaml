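# Adult brain tissue parameters at 7T.
# T1/T2 in ms, PD relative, D apparent diffusion coefficient in mm^2/s.
WM:
  T1: 1220
  T2: 45.9
  PD: 0.69
  D: 0.70e-3
GM:
  T1: 2132
  T2: 55
  PD: 0.82
  D: 0.80e-3
CSF:
  T1: 3350
  T2: 1000
  PD: 1.0
  D: 3.0e-3
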