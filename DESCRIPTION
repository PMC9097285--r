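Package: amidemap
Title: Amide-I Exciton Hamiltonians from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts atomistic protein molecular dynamics trajectories into
    time-dependent amide-I vibrational exciton Hamiltonians for infrared
    spectroscopy modelling. Detects backbone and side-chain amide-I
    chromophores (including cyclic and multichain proteins), evaluates the
    electrostatic potential, field and gradient at the amide atoms from
    surrounding point charges, applies pluggable electrostatic frequency maps
    and Ramachandran nearest-neighbour corrections, computes transition-dipole
    and transition-charge couplings, and writes Hamiltonian, dipole and
    position trajectories in the binary layout consumed by time-domain
    spectral engines. Includes isotope-label postprocessing, a minimal
    time-domain linear-absorption calculator for end-to-end verification, and
    deterministic synthetic peptide fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
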