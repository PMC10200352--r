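Package: qmmvib
Title: Harmonic Vibrational Spectroscopy for Embedded Molecular Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculator-agnostic machinery for harmonic vibrational analysis
    of molecules and embedded (QM/MM-style) clusters: numerical Hessians and
    dipole/polarizability derivatives by two-point central differences with
    deterministic work-group dispatch, normal-mode analysis over a
    vibrationally active region, double-harmonic infrared intensities,
    Raman and resonance-Raman scattering activities from polarizability
    invariants, electrostatic and core-shell polarizable embedding with
    iterative mutual polarization, Lorentzian-broadened spectra, Molden
    output, and isotope restarts by amendment of atomic masses. Bundled
    analytic model potentials (Morse/charge-flux diatomic, centrosymmetric
    triatomic, shell-model ionic engine) serve as verifiable property
    providers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
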