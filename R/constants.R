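## Physical constants (CODATA 2018). Internal unit conventions:
## positions nm, charges e, dipoles Debye, energies/frequencies cm^-1,
## electrostatics in atomic units at the point of map evaluation.

#' @keywords internal
.const <- local({
  e_C      <- 1.602176634e-19          # elementary charge, C
  h_Js     <- 6.62607015e-34           # Planck, J s
  c_ms     <- 2.99792458e8             # speed of light, m/s
  eps0     <- 8.8541878128e-12         # vacuum permittivity, C^2 J^-1 m^-1
  bohr_nm  <- 0.052917721090380        # Bohr radius, nm
  debye_Cm <- 1e-21 / c_ms             # 1 Debye in C m
  hc_Jcm   <- h_Js * c_ms * 100        # h*c with nu-tilde in cm^-1, J cm

  list(
    bohr_nm    = bohr_nm,
    hartree_cm = 219474.6313632,
    c_cm_fs    = c_ms * 100 * 1e-15,   # speed of light, cm/fs
    # Eq.-2 style prefactor: J [cm^-1] = tdc_prefactor * (dipole term [D^2 nm^-3])
    tdc_prefactor = debye_Cm^2 / (4 * pi * eps0 * 1e-27 * hc_Jcm),
    # Coulomb energy of two unit charges 1 nm apart, cm^-1
    coulomb_cm = e_C^2 / (4 * pi * eps0 * 1e-9 * hc_Jcm),
    # 1 e nm expressed in Debye
    enm_debye  = e_C * 1e-9 / debye_Cm
  )
})

#' Unit-conversion constant of the point-dipole coupling formula
#'
#' The transition-dipole coupling between two point dipoles is
#' \deqn{J = \frac{A}{\epsilon_r}\,
#'   \frac{\mu_i\cdot\mu_j - 3(\mu_i\cdot\hat r)(\mu_j\cdot\hat r)}{r^3}}
#' with dipoles in Debye and the separation in nm. `tdc_prefactor()` returns
#' the constant \eqn{A} (about 5.034 cm\eqn{^{-1}} nm\eqn{^3} D\eqn{^{-2}}),
#' computed from CODATA constants.
#'
#' @return Numeric scalar, cm^-1 nm^3 D^-2.
#' @export
tdc_prefactor <- function() .const$tdc_prefactor
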