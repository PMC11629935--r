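# Reduced 10x10 version of the baseline acquisition; all other parameters
# at their defaults (0.05 nm step, 10 us dwell, Ds = 0.01 nm^2,
# D = 10 nm^2/s, Q0 = 63.45 Mu/s).
grid:
  nx: 10
  ny: 10
  step_nm: 0.05
dwell_us: 10
settle_us: 0
probe:
  Ds_nm2: 0.01
  Q0_Mu_s: 63.45
medium:
  D_nm2_s: 10
sim:
  subpixels: 10
  NT: 1
  margin_steps: 5
trajectory: raster
seed: 1
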