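# MP2RAGE protocol presets.
# Times in ms, flip angles in degrees.  nInner is the full matrix size of
# the inner (partition) phase-encode loop; with linear ordering and the
# given partial Fourier fraction, the excitations per block and the
# k-space-center index follow as nInner*pf and round(nInner*(pf - 1/2)).
# n_outer/grappa/acs_lines/pf_outer drive the scan-duration estimate.

screening_tr4000:   # TI/FA screening protocol, TR 4000 ms
  TR_MP2RAGE: 4000
  TR_GRE: 7.26
  TE: 3.15
  TI1: 650
  TI2: 2220
  alpha1: 5
  alpha2: 4
  nInner: 240
  pf_inner: 0.75
  voxel_size: 0.65
  n_outer: 320
  pf_outer: 0.75
  grappa: 3
  acs_lines: 40

screening_tr4500:
  TR_MP2RAGE: 4500
  TR_GRE: 7.26
  TE: 3.15
  TI1: 650
  TI2: 2220
  alpha1: 5
  alpha2: 6
  nInner: 240
  pf_inner: 0.75
  voxel_size: 0.65
  n_outer: 320
  pf_outer: 0.75
  grappa: 3
  acs_lines: 40

screening_tr5000:
  TR_MP2RAGE: 5000
  TR_GRE: 7.26
  TE: 3.15
  TI1: 650
  TI2: 2220
  alpha1: 5
  alpha2: 7
  nInner: 240
  pf_inner: 0.75
  voxel_size: 0.65
  n_outer: 320
  pf_outer: 0.75
  grappa: 3
  acs_lines: 40

final:              # 0.65 mm isotropic joint UNI + FLAWS protocol
  TR_MP2RAGE: 4000
  TR_GRE: 7.9
  TE: 3.15
  TI1: 650
  TI2: 2280
  alpha1: 4
  alpha2: 5
  nInner: 256
  pf_inner: 0.75
  voxel_size: 0.65
  n_outer: 320
  pf_outer: 1.0
  grappa: 4
  acs_lines: 40

low_b1_sensitive:   # 1 mm low-B1+-sensitivity comparison protocol
  TR_MP2RAGE: 8000
  TR_GRE: 6.9
  TE: 3.07
  TI1: 1000
  TI2: 3300
  alpha1: 4
  alpha2: 5
  nInner: 160
  pf_inner: 0.75
  voxel_size: 1.0
  n_outer: 208
  pf_outer: 1.0
  grappa: 3
  acs_lines: 40

flaws_0p8mm:        # 0.8 mm FLAWS-optimized comparison protocol
  TR_MP2RAGE: 5000
  TR_GRE: 5
  TE: 2.06
  TI1: 620
  TI2: 1430
  alpha1: 4
  alpha2: 8
  nInner: 192
  pf_inner: 0.75
  voxel_size: 0.8
  n_outer: 300
  pf_outer: 1.0
  grappa: 3
  acs_lines: 40
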