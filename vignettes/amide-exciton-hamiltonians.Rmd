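---
title: "From MD trajectories to amide-I exciton Hamiltonians: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From MD trajectories to amide-I exciton Hamiltonians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amidemap)
```

## The model

Protein amide-I infrared spectroscopy is described by a time-dependent
one-exciton Hamiltonian over the local amide-I modes (the backbone C=O
stretch vibrations, plus the primary amides of Gln/Asn side chains):

$$H(t) = \sum_i \omega_i(t)\, B_i^\dagger B_i
       + \sum_{i \ne j} J_{ij}(t)\, B_i^\dagger B_j
       - \sum_i \frac{\Delta_i}{2}\, B_i^\dagger B_i^\dagger B_i B_i ,$$

where $\omega_i(t)$ is the fluctuating site frequency, $J_{ij}(t)$ the
inter-site coupling, and $\Delta_i$ the site anharmonicity (only relevant for
doubly excited states probed by 2D infrared spectroscopy). `amidemap`
extracts $\omega_i$, $J_{ij}$, the transition dipoles $\mu_i$ and the site
positions frame by frame from an atomistic MD trajectory and writes them in
the binary trajectory layout consumed by time-domain spectral engines.

### Site frequencies: electrostatic maps

The site frequency is predicted by a *map*, a linear form in the
electrostatic potential, field and field gradient generated by the
surrounding partial charges at the amide C, O, N and (for secondary amides)
H/D atoms:

$$\omega_i = \omega_0 + \sum_{a \in \{C,O,N,H\}} \sum_k
  c_{a,k}\, E_{a,k},$$

with $E_{a,k}$ the electrostatic components in atomic units and $c_{a,k}$
the map coefficients (cm$^{-1}$ per a.u.). Two conventions matter and are
fixed here explicitly:

* **Local frame.** Field and gradient components are contracted in the
  local amide frame — $x$ along C=O, $z$ normal to the O=C–N plane, $y$
  completing a right-handed set. Without this the predicted frequency would
  depend on the molecule's orientation in the box. The lab-frame
  electrostatics are rotated into this frame before map evaluation.
* **Field gradient.** The gradient tensor is $\nabla E$ (the Jacobian of
  the field), symmetric and traceless for external sources.

The engine is value-agnostic: coefficients are data, loaded from a YAML map
schema documented by the commented files under
`system.file("extdata", "maps", package = "amidemap")`. The shipped maps are
*synthetic demonstration maps* with realistic orders of magnitude; published
literature map coefficients can be transcribed into the same schema by the
user. Tests deliberately use synthetic maps so that correctness of the
machinery never depends on a transcription.

### Electrostatics: cutoffs and exclusions

Sources are point partial charges. A source within the map cutoff (default
2 nm, a common production choice) of the unit's carbonyl carbon contributes
to *all* map atoms of that unit; a single per-unit inclusion decision avoids
the discontinuities a per-atom cutoff would create. Minimum-image
periodicity is applied in orthorhombic boxes; there is no Ewald summation —
maps are parametrized against plainly truncated sums. A reusable neighbor
list (default 2.5 nm search radius, rebuilt every 50 frames) provides a
superset of candidate sources; the margin over the map cutoff absorbs both
the intra-unit extent and solvent motion between rebuilds.

Excluded from a unit's electrostatics are, by default, all atoms of the two
residues forming the unit plus the immediately preceding and following
backbone residues: their influence is carried by the nearest-neighbour maps
instead, and double counting them as point charges would be inconsistent.
Published map families differ in their exact exclusion conventions, so the
rule is part of the map file schema (`nearest_residues`, `own_residue`,
`none`) rather than hard-coded.

### Nearest-neighbour corrections

Electrostatics is a poor model for the covalently adjacent amide group.
For backbone-adjacent pairs, DFT-derived Ramachandran lookup tables supply
a frequency shift for each member of the pair and the pair coupling, as a
function of the $(\phi, \psi)$ of the shared residue, interpolated
*bilinearly* with periodic wrap at $\pm 180^\circ$. Nearest-neighbour
corrections apply only between backbone-linked units; side-chain amides are
not backbone-linked and receive none (where their couplings to everything
are computed through space).

### Amide classes

Three chromophore classes are recognized: ordinary *secondary* backbone
amides; *tertiary* amides preceding proline (no N–H; in runs of consecutive
prolines every preproline bond is tertiary); and *primary* side-chain
amides of Gln and Asn. When a class lacks its own map, the secondary-amide
map is used and corrected by an empirical class shift: $-27$ cm$^{-1}$ for
preproline and $+30$ cm$^{-1}$ for primary amides. Both are user-settable
(`pipeline_config(preproline_shift =, sidechain_shift =)`), and a
class-specific map, when supplied, bypasses the shift entirely.

The N-terminal backbone unit (no preceding residue) gets no special
treatment: it is a plain secondary amide whose nearest-neighbour correction
on the missing side is simply zero. Chain connectivity is detected from
C–N distances (< 0.2 nm) in the reference frame, which makes recognition
robust for multichain systems and closes head-to-tail bonded chains into
cycles.

### Couplings

Non-neighbour couplings come from one of two through-space schemes:

* **TDC** (transition-dipole coupling), the point-dipole formula
  $J_{ij} = \frac{A}{\epsilon_r}\,
  \frac{\mu_i\cdot\mu_j - 3(\mu_i\cdot\hat r)(\mu_j\cdot\hat r)}{r^3}$ with
  $A \approx 5.034$ cm$^{-1}$ nm$^3$ D$^{-2}$ computed from CODATA
  constants and frozen behind `tdc_prefactor()` (the formula's units are
  otherwise easy to get silently wrong).
* **TCC** (transition-charge coupling), a Coulomb double sum over per-atom
  transition charges, which retains the higher multipole moments of the
  transition density and reduces to TDC at long range (verified to within
  0.1% at 10 nm in the test suite).

Both scale as $1/\epsilon_r$ (default 1, the value that has worked well
against experiment). Nearest-neighbour pairs bypass the through-space
scheme in favour of the DFT-quality grid value by default; the grid values
derive from vacuum dimer calculations and are *not* divided by
$\epsilon_r$. Only the minimum image of a pair couples; no lattice sums.
Couplings below a prune threshold (default 0.01 cm$^{-1}$, the usual choice
when preparing 2DIR input) are zeroed.

The transition dipole is a rigid construction from the map's dipole model:
magnitude (default 0.37 D, the accepted amide-I transition-dipole
strength), in-plane angle from the C=O axis (positive toward N), and an
origin offset along C=O from the carbon. The recorded site position is the
carbonyl carbon.

### Anharmonicity and isotope labels

The anharmonicity is a per-site constant, default 16 cm$^{-1}$; it does not
fluctuate appreciably in practice and no map for it is provided. It is
recorded in the run report rather than per frame.

Isotope editing is a postprocess on the Hamiltonian trajectory: the
empirical shifts $-41$ cm$^{-1}$ ($^{13}$C) and $-66$ cm$^{-1}$
($^{13}$C$^{18}$O) are the default mode; a reduced-mass scaling of the C=O
oscillator ($\omega \to \omega\sqrt{\mu_{12}/\mu_{13}}$) is available for
sensitivity checks. `truncate_to_labels()` implements the common
approximation that labelled units decouple, extracting the labelled
sub-block (eigenvalues of the block equal those of the full matrix with
unlabelled couplings zeroed — a tested invariant). Deuteration (amide-I vs
amide-I$'$) is *not* an isotope postprocess: it changes the map physics and
must be handled by choosing a deuterated-amide map.

## Linear absorption for verification

The package carries a minimal time-domain linear-absorption calculator so
Hamiltonian trajectories can be verified end to end without an external
spectral engine. The first-order response is

$$S(t) \propto \left\langle \mu(t_0 + t)\, U(t_0 + t, t_0)\, \mu(t_0)
\right\rangle_{t_0} e^{-t/2T_1},$$

propagated with the exact symmetric-matrix exponential per 20 fs step
(system sizes here are small, so no Trotter splitting is needed),
frequencies recentred at the window midpoint to avoid fast phase rotation,
averaged over equidistant starting points, and damped by
$e^{-t/2T_1}$ — the *population* lifetime convention, i.e. the coherence
decays at half the population rate ($T_1$ default 1.8 ps). The spectrum is
the real part of the half-sided Fourier transform on the window (default
1550–1750 cm$^{-1}$), with trapezoidal quadrature. Defaults mirror common
practice: coherence times 0–2.56 ps in 20 fs steps, 1000 equidistant
starting points.

`overlap_shift()` aligns a simulated spectrum with a reference by scanning
rigid shifts at grid resolution, maximizing the inner product of the
unit-normalized spectra, refined by parabolic interpolation. Sign
convention: the returned value is the shift *added to the simulated axis*
for best overlap, so a positive value means the simulation sits to the red
of the reference.

Three verified spectroscopic properties tie everything together: a static
site is a Lorentzian of FWHM $(2\pi c T_1)^{-1}$; static coupled sites peak
at the exciton eigenvalues; and the integrated intensity of uncoupled sites
is proportional to $\sum_i |\mu_i|^2$ (sum rule, tested to 1%).

## The synthetic fixture generator

All tests run on generated fixtures — no downloads, no binary data:

* Ideal peptide geometries built from standard bond lengths/angles by
  natural-extension chain growth at prescribed dihedrals (helix
  $-57/-47^\circ$, sheet $-139/135^\circ$), with minimal Pro/Asn/Gln side
  chains so all three amide classes occur; a planar-ring construction for
  cyclic peptides; and a two-unit dimer at a controllable separation for
  coupling scans.
* A point-charge solvent shell (default charge magnitude 0.4 e, placed at
  least 0.3 nm from the peptide) whose positions follow an
  Ornstein–Uhlenbeck process, sampled at 20 fs with a 50 fs correlation
  time and 0.02 nm displacement scale. This reproduces the *statistical
  structure* relevant for amide-I line shapes — sub-100-fs frequency
  fluctuations that produce motional narrowing — which the suite verifies
  by recovering the correlation time from the generated site-frequency
  series and by the narrowing of the frequency-jump line with increasing
  jump rate.
* Fixtures are written in the same GRO/charge-table formats the pipeline
  reads, so file I/O is tested for free; fixed seeds make them
  byte-reproducible.

What passing these tests does and does not show: the machinery — detection,
electrostatics, map algebra, couplings, file formats, propagation — is
verified against independent oracles; but the fixtures are not
force-field-quality dynamics, and the shipped demonstration maps are not
literature parametrizations, so absolute spectra from the demo set are
illustrative, not predictive. Predictive work requires a real MD trajectory
plus transcribed literature maps.

## Numerical choices and edge cases

* Positions are kept in nm, charges in e; electrostatics are converted to
  atomic units at map evaluation, matching published coefficient
  conventions. Double precision in memory; IEEE-754 single precision on
  disk (the spectral-engine convention), with a text mirror of each format
  as the interchange escape hatch since downstream engines differ in byte
  layout expectations.
* Dihedrals follow the IUPAC convention in $[-180^\circ, 180^\circ)$,
  cross-validated against an independent reference implementation.
* Degenerate amide geometry (collinear C, O, N) aborts with the frame and
  unit named; sources closer than 0.05 nm to a map atom warn (clash) but
  still contribute; TCC atom pairs below 0.02 nm are an error.
* Missing backbone C/O/N in a peptide bond is a hard error naming the
  residue; unknown residue names are skipped with a warning unless declared
  in a user residue-extension file (which can also add side-chain amide
  definitions for nonstandard residues).
* Frame time stamps come from the trajectory when present, else
  frame index × 20 fs.
* Problem sizes in the test and acceptance runs are chosen for desk-scale
  verification: peptides of 2–58 residues, tens of point charges, hundreds
  to a few thousand frames, 100-instance oracle sweeps. These sizes
  exercise every code path; production systems differ only in scale.

## Known limitations

Orthorhombic boxes only; no polarizable force fields or reaction-field
corrections; no coupling changes upon isotope labelling; no anharmonicity
map; 2DIR/VCD spectra and Raman/sum-frequency polarizabilities are out of
scope (the written trajectories are the interface to dedicated spectral
engines); serial execution.
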