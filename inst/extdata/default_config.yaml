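# All-defaults run description. Every key is optional; values shown here
# are the package defaults. Concentrations in M, rates in SI units.
constants:
  k1: 1.7e7        # CATFeIII + H2O2 -> compound I, M-1 s-1
  k2: 2.6e7        # compound I + H2O2 -> CATFeIII + O2, M-1 s-1
  k3: 1.1e3        # NO2- + H2O2 + H+ -> ONOOH, M-2 s-1
  pka: 6.8         # ONOOH acid dissociation
  k_minus4: 1.0e10 # ONOO- + H+ -> ONOOH, M-1 s-1
  k5: 1.7e6        # catalase-mediated ONOO- decomposition, M-1 s-1
  k6: 5.8e4        # ONOO- + CO2, M-1 s-1
  kP: 1.0e-7       # mitochondrial H2O2 production, M s-1
  kD4: 320         # ONOO- membrane diffusion, s-1
  kD5: 320         # NO2- membrane diffusion, s-1
  kD7: 320         # ONOOH membrane diffusion, s-1
phenotype:
  kd1: 920         # H2O2 membrane diffusion, s-1
  cat0: 1.0e-6     # intracellular catalase, M
scenario:
  regime: selective_nonsynergistic
time_grid:
  t1: 1.0e-2
  t2: 1.0
  tf: 100.0
  dt1: 1.0e-7
  dt2: 1.0e-5
  dt3: 1.0e-3
solver:
  rtol: 1.0e-8
  atol: 1.0e-22
grid:
  kd1_min: 100
  kd1_max: 2000
  kd1_steps: 100
  cat0_min: 1.0e-8
  cat0_max: 1.0e-5
  cat0_steps: 100
  kd1_spacing: linear
  cat0_spacing: linear
output:
  out_dir: .
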