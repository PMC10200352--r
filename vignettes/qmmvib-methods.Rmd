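---
title: "Harmonic IR and Raman spectra of embedded systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic IR and Raman spectra of embedded systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmvib)
```

# Scope and model

`qmmvib` computes harmonic vibrational spectra — frequencies, infrared
intensities, and (resonance) Raman scattering activities — for molecules
and for chemically active regions embedded in a classical environment.
The machinery is calculator-agnostic: anything that fulfils the
property-provider contract (`evaluate()` returning energy, gradient,
dipole, and optionally a complex polarizability) can drive it.  The
package bundles three analytic model engines whose derivatives are known
in closed form; they play the role that electronic-structure and
forcefield drivers play in production embedding codes, and double as
exact oracles for the numerical machinery.

The physical model is the standard additive embedding decomposition

$$E_\mathrm{total} = E_\mathrm{inner} + E_\mathrm{env} + E_\mathrm{coupling},$$

with the environment represented to the inner region as point charges
(electrostatic embedding) or as core–shell pairs whose shells relax
self-consistently with the inner region (polarizable embedding).  The
potential energy surface is expanded to second order in the Cartesian
coordinates of the $N$ vibrationally active atoms only, giving $3N$
normal modes.  For an embedded fragment the nominally translational and
rotational motions are genuine vibrations — the environment breaks the
free-molecule invariances — so no rigid-body projection is applied by
default; `project_tr = TRUE` restores free-molecule behaviour (exactly
6, or 5 for linear arrangements, zero modes).

## Intensities in the double harmonic approximation

Truncating the dipole expansion along each normal mode $Q_i$ at linear
order, the IR absorption strength of mode $i$ is proportional to
$|\partial\mu/\partial Q_i|^2$.  The package reports the raw squared
derivative (e²/amu) and a km/mol value using the conventional conversion
$A = N_A |\partial\mu/\partial Q|^2 / (12\,\epsilon_0 c^2)$; the
experimental set-up form factor and radiation density are deliberately
omitted, so relative intensities are the contract.

Raman activities use the rotational invariants of the polarizability
derivative tensor $\alpha' = \partial\alpha/\partial Q_i$:

$$\bar\alpha' = \tfrac13(\alpha'_{xx} + \alpha'_{yy} + \alpha'_{zz}),
\qquad
\beta'^2 = \tfrac12\big[(\alpha'_{xx}-\alpha'_{yy})^2 +
(\alpha'_{yy}-\alpha'_{zz})^2 + (\alpha'_{zz}-\alpha'_{xx})^2 +
6(\alpha'^2_{xy}+\alpha'^2_{xz}+\alpha'^2_{yz})\big],$$

combined into the scattering factor $S = 45\bar\alpha'^2 + 7\beta'^2$.
Both unscaled activities (Å⁴/amu) and activities scaled by the squared
harmonic transition matrix element
$|\langle 0|Q|1\rangle|^2 = \hbar/(2\omega)$ are always emitted, because
conventions differ between codes about whether the transition moment is
included.  For resonance Raman the polarizability is complex; every
squared term in the invariants becomes a squared modulus.  We read the
"same method applies on and off resonance" convention this way because
it is the only reading that reduces continuously to the static formulas
as the imaginary part vanishes.

## Finite differences and task farming

Second derivatives of the energy and first derivatives of the dipole and
polarizability are obtained by two-point central differences over the
$3N$ active Cartesian coordinates ($6N$ single-point evaluations).  The
coordinate list is split into $M$ work groups; because aggregation order
is fixed by coordinate index and every calculator is a pure function of
geometry, the assembled `derivative_bundle` — and every file derived
from it — is bit-identical for any $M$.  The serial executor used here
realizes that contract directly; a concurrent executor honouring the
same aggregation order would produce identical bytes.

**Displacement coordinates.** Displacements are applied in plain
Cartesian coordinates and mass weighting is applied analytically
afterwards.  Mass-weighted displacement sweeps would bake the masses
into the stored derivatives and forbid isotope restarts; with Cartesian
storage, an isotope study is a pure post-processing step
(`remass_restart()`), asserted in the tests to perform zero new
calculator calls.

**Step size.** The default step is 0.01 Bohr.  On the Morse model the
frequency error at this step is below 0.01% and falls by a factor of
about 4 when the step halves, confirming the expected $O(h^2)$
behaviour of central differences.  The step is configurable; rotation
invariance checks in the test suite use $10^{-4}$ Bohr because the
$O(h^2)$ bias of an anharmonic potential is orientation-dependent and
must be pushed below the comparison threshold.

**Degenerate modes.** Within a degenerate frequency level the
eigenvector basis is arbitrary; per-mode intensities inside a level are
therefore basis-dependent, while their sum is invariant.  Tests compare
level sums.  The reported mode vectors use a deterministic sign
convention (largest-magnitude component positive, ties broken by lowest
index) so spectra files are reproducible.

**Guard rails.** The raw Hessian's maximum asymmetry is recorded and an
error is raised above $10^{-4}$ Hartree/Bohr² — a symptom of
inconsistent calculator gradients, not of the sweep.  Frequencies below
1 cm⁻¹ are counted as zero for reporting only; no modes are dropped.

# The bundled model calculators

These models are the package's synthetic study systems.  They emulate
the *mathematical structure* of embedded vibrational problems — bonded
anharmonicity, charge flux, bond polarizability, resonance response,
ionic polarization — with parameters in the range of real systems
(force constants of a few tenths of a Hartree/Bohr², partial charges of
a few tenths of e, electronic resonances of a few tenths of a Hartree).
What they do not emulate is the electronic many-body problem: there is
no self-consistent charge density, no charge transfer across the
boundary, and no covalent cross-boundary bonding (no link atoms).
Passing tests therefore validate the vibrational and embedding
machinery, not any electronic-structure approximation.

* **Diatomic (Morse or harmonic, charge flux, bond polarizability).**
  $V = D(1-e^{-a(r-r_0)})^2$ (harmonic force constant $k = 2Da^2$) or
  $\tfrac12 k (r-r_0)^2$; charges $\mp q(r)$ with
  $q(r) = q_0 + q_1 (r - r_0)$, so $\mu = q(r)\,\mathbf{r}$; axial and
  transverse bond polarizabilities linear in $r - r_0$.  An optional
  electronic resonance $\omega_e$ multiplies the static tensor by the
  damped-Lorentzian factor
  $\omega_e^2/(\omega_e^2 - \omega^2 - i\Gamma\omega)$, which recovers
  the static tensor exactly at $\omega = 0$ and gives the on-resonance
  enhancement $(\omega_e/\Gamma)^2$ in the activity.  The default
  damping $\Gamma = 0.006$ a.u. is the conventional empirical
  excited-state lifetime parameter.  The functional form of this
  frequency dependence is a deliberately simple stand-in for a full
  response calculation and is flagged as such.

* **Centrosymmetric triatomic (A–B–A).**  Two harmonic bonds, fixed
  charges ($q_B = -2q_A$, neutral), additive bond polarizabilities.
  The bend is implemented as $k_\theta(1 + \cos\theta)$ rather than
  $\tfrac12 k_\theta(\pi - \theta)^2$: the two agree to quadratic order
  at linearity, but $\cos\theta$ has smooth Cartesian derivatives where
  $\arccos$ is singular.  By symmetry the asymmetric stretch is
  IR-active and Raman-silent and the symmetric stretch the reverse —
  the classic mutual-exclusion fixture, asserted to leak less than
  $10^{-8}$ of the active intensity.

* **Shell-model ionic engine.**  Cores with fixed charges; optional
  massless shells bound by harmonic springs (isolated-ion
  polarizability exactly $q_s^2/k$); Coulomb interactions between all
  sites of distinct atoms; optional Buckingham short-range terms
  between repulsion sites.  Shells are relaxed at every evaluation by a
  spring-preconditioned fixed-point iteration
  ($\Delta d = -f_\mathrm{shell}/k$ per cycle, converged when the
  per-cycle displacement change drops below $10^{-7}$ Bohr).  The
  iteration is deterministic and independent of the starting point
  within the quadratic basin; for a purely quadratic shell energy it
  solves the linear system exactly at convergence, and it degrades
  gracefully when Buckingham terms make the energy only approximately
  quadratic.  Polarizability of shell systems is defined operationally
  as the finite-field dipole response (default field step $10^{-3}$
  a.u.), cross-checked in the tests against brute-force energy
  minimization.

# Embedding

`compose_additive()` builds a composite calculator from an inner
calculator, a shell-model environment engine, and a region map
partitioning atoms into inner, active-environment and
frozen-environment sets (frozen atoms contribute charges but never
move).  The inner region sees environment cores and shells as external
charges; forces on environment atoms combine the environment engine's
internal gradients with the gradients the inner calculator reports on
external charges.  Because shells are at their energy minimum when
gradients are taken, Hellmann–Feynman applies and no shell-response
terms are needed.

For polarizable embedding the composite alternates shell relaxation (in
the field of the inner region's point charges) with inner evaluation
(in the field of cores and relaxed shells).  The inner region is
represented to the shells by its effective point charges — a documented
simplification of a self-consistent charge density, exact for the
bundled models whose charge distribution *is* a set of point charges.
Convergence is declared when the inner dipole moves by less than
$10^{-8}$ e·Bohr between outer iterations (the convergence criterion
and the relaxation ordering are design choices of this package; the
dipole is the natural observable because it is what the spectroscopy
consumes).  A non-polarizable inner region converges in one outer
iteration; warm-starting from a converged state also reconverges in
one.  Two invariants are asserted for every fixture: the additive
decomposition holds to $10^{-12}$ Hartree, and polarizable embedding
never raises the total energy relative to the rigid-shell electrostatic
result at the same geometry (shell relaxation is variational).

# Spectra and artifacts

Stick spectra are broadened with area-normalized Lorentzians of FWHM
$\gamma$ (default 20.0 cm⁻¹, with 10.0 cm⁻¹ a common alternative for
resonance work), so a unit peak has height $2/(\pi\gamma)$ and unit
integral; normalization conventions vary between codes, so this choice
is documented and tested rather than assumed.  Peak tables, spectrum
CSVs and Molden normal-mode files use fixed-precision formatting;
identical runs are byte-identical.  The restart archive is versioned
JSON with numbers written at 17 significant digits, which round-trips
IEEE doubles exactly.

`run_task()` drives the whole pipeline from a YAML config (the
`qmmvib` script exposes `run` and `restart` subcommands); `ir`, `raman`
and `resonance_raman` flags select which intensities are computed, and
stage failures propagate with the stage label.

# Problem sizes and limitations

The test suite and the acceptance script run on fixtures of 1–3 atoms
with up to two shells; these sizes make every quantity checkable
against closed forms or brute-force minimization while exercising every
code path (the sweep cost is $6N$ single points regardless of the
model).  Known limitations, by construction: no link atoms or boundary
charge corrections (fixtures have no covalent cross-boundary bonds); no
periodic electrostatics (finite clusters only); no anharmonic
corrections beyond what the Morse fixture exposes through the
convergence tests; the frequency dependence of the model polarizability
is a damped Lorentzian, not a response calculation; depolarization
ratios and absolute cross sections are not computed.
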