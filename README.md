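# qmmvib

Harmonic vibrational spectroscopy for molecules and embedded
(QM/MM-style) chemical systems: numerical Hessians and property
derivatives by task-farmed central differences, normal-mode analysis
over a vibrationally active region, double-harmonic IR intensities,
Raman and resonance-Raman scattering activities, electrostatic and
core–shell polarizable embedding, Lorentzian-broadened spectra, Molden
output, and isotope restarts by amendment of atomic masses.

The package is for method developers and computational spectroscopists
who need the *vibrational* machinery — derivative sweeps, mode analysis,
intensity formulas, embedding composition — decoupled from any
particular electronic-structure backend.  Any property provider that
fulfils the calculator contract (energy, gradient, dipole, complex
polarizability on request) can drive it; three analytic model engines
with closed-form derivatives are bundled, so every piece of the
machinery is verifiable against exact results on one CPU.

## The method in brief

For a system partitioned into an inner region and an environment the
energy is additive,

    E_total = E_inner + E_env + E_coupling ,

with the environment entering the inner calculation as point charges
(electrostatic embedding) or as core–shell pairs relaxed to mutual
self-consistency with the inner region (polarizable embedding; an
isolated core–shell ion has polarizability q_s²/k).  The potential
energy surface is expanded to second order in the Cartesian coordinates
of the N vibrationally active atoms.  The Hessian and the dipole /
polarizability derivatives are built from two-point central differences
(6N single points, dispatched over M work groups with order-independent,
bit-identical aggregation), mass-weighted analytically, and
diagonalized; derivatives are projected onto modes by the chain rule,

    dmu/dQ_i = sum_k (dmu/dx_k) m_k^(-1/2) L_ki .

Per mode, the IR intensity is |dmu/dQ|² (reported raw and in km/mol)
and the Raman scattering factor is

    S = 45 * abar'^2 + 7 * beta'^2

from the isotropic and anisotropic invariants of dalpha/dQ, with
squared moduli for complex (damped resonance) tensors; both unscaled
(Å⁴/amu) and hbar/(2*omega)-scaled activities are emitted.  Because the
sweep stores plain Cartesian derivatives, isotope studies are restarts:
amend the masses, rediagonalize, zero new calculator calls.

## Worked example

The bundled example task computes the IR and Raman spectrum of a
harmonic charge-flux diatomic (k = 0.5 Hartree/Bohr², r0 = 2 Bohr,
q0 = 0.3 e, bond polarizability model, electronic resonance at
0.3 Hartree):

```r
library(qmmvib)
cfg <- system.file("extdata", "task_h2.yaml", package = "qmmvib")
res <- run_task(cfg, "h2_out")
res$peaks
#>   mode    frequency       ir_raw    ir_km_mol raman_unscaled raman_scaled
#> 1    1 4.231549e-07 5.624787e-33 5.483493e-30   1.506185e-32 6.000333e-25
#> 2    2 1.660580e-05 1.263032e-25 1.231305e-22   5.777013e-25 5.864622e-19
#> 3    3 1.326738e-04 3.245064e-33 3.163548e-30   1.173097e-32 1.490546e-27
#> 4    4 1.809878e+01 1.785714e-01 1.740857e+02   8.168045e-01 7.607910e-01
#> 5    5 1.809878e+01 1.785714e-01 1.740857e+02   8.168045e-01 7.607910e-01
#> 6    6 5.120048e+03 1.785714e-01 1.740857e+02   7.281483e-01 2.397410e-03
```

All 3N = 6 modes are reported.  Modes 1–3 are the numerically zero
translations; modes 4–5 are the free-rotor pair (an O(step²)
finite-difference artifact at 18 cm⁻¹, which vanishes under
`project_tr = TRUE` and becomes a genuine libration once the molecule
is embedded); mode 6 is the stretch at 5120 cm⁻¹ = sqrt(k/mu) with
mu = 0.504 amu.  Its raw IR intensity 0.17857 e²/amu is exactly
q²/mu = 0.09/0.504, i.e. 174.1 km/mol.  The output directory contains
`peaks.csv`, `spectrum_ir.csv`, `spectrum_raman.csv` (Lorentzian FWHM
20 cm⁻¹), `modes.molden`, a JSON `restart.json` archive and a
`summary.json` run record.

A deuteration study from the stored sweep, without re-evaluating the
calculator:

```sh
qmmvib restart h2_out/restart.json --masses 2.016,2.016 --out h2_d2
#> modes (cm^-1): ... 3.6204205e+03     # = 5120.05 / sqrt(2)
```

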