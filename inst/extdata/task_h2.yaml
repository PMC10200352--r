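# Example task: IR + Raman spectrum of the bundled model diatomic.
# Calculator parameters are in atomic units (Hartree, Bohr, e).
structure: h2_model.xyz
calculator:
  model: diatomic
  params:
    potential: harmonic
    k: 0.5          # Hartree/Bohr^2
    r0: 2.0         # Bohr
    q0: 0.3         # e
    alpha_par: [2.0, 0.5]
    alpha_perp: [1.0, 0.2]
    omega_e: 0.3    # Hartree; enables the damped resonance model
task:
  ir: true
  raman: true
  step: 0.01        # Bohr
  workgroups: 1
  bandwidth: 20.0   # cm^-1 FWHM
  grid: {from: 0.0, to: 6000.0, by: 2.0}
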