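# Shared test helpers: in-code fixtures, synthetic maps, small oracles.

# Hamiltonian frame built directly from numbers (bypasses the pipeline).
mkframe <- function(omega, J = matrix(0, length(omega), length(omega)),
                    mu = NULL, pos = NULL, t = 0, anh = 16) {
  n <- length(omega)
  if (is.null(mu)) mu <- cbind(rep(1, n), 0, 0)
  if (is.null(pos)) pos <- matrix(0, n, 3)
  structure(list(time = t, omega = omega, J = J,
                 anharmonicity = rep(anh, n), dipoles = mu, positions = pos),
            class = "hamiltonian_frame")
}

# Simple potential-only map used across tests.
test_map <- function(omega0 = 1650, angle = 20, magnitude = 0.37) {
  electrostatic_map(
    "test", omega0,
    coefficients = list(C = c(potential = 1800),
                        O = c(potential = -3000, field_x = 1500),
                        N = c(potential = 1200)),
    dipole = list(magnitude = magnitude, angle = angle, offset = 0),
    transition_charges = consistent_tq(magnitude, angle)
  )
}

# Transition charges on C/O/N whose implied dipole reproduces the dipole
# model exactly for the ideal fixture amide geometry (O=C-N angle from the
# builder's internal coordinates).
consistent_tq <- function(magnitude = 0.37, angle = 20) {
  ocn <- (360 - 120.5 - 116.6) * pi / 180
  rO <- c(0.1229, 0)
  rN <- 0.1329 * c(cos(ocn), sin(ocn))
  mu <- magnitude / 48.03204707 * c(cos(angle * pi / 180),
                                    sin(angle * pi / 180))
  qN <- mu[2] / rN[2]
  qO <- (mu[1] - qN * rN[1]) / rO[1]
  c(C = -(qO + qN), O = qO, N = qN)
}

# Random field sample in an arbitrary frame (gradient symmetric+traceless).
random_field_sample <- function(roles = c("C", "O", "N", "H")) {
  fs <- lapply(roles, function(r) {
    A <- matrix(rnorm(9), 3, 3)
    G <- (A + t(A)) / 2
    diag(G) <- diag(G) - sum(diag(G)) / 3
    list(potential = rnorm(1), field = rnorm(3), gradient = G,
         position = rnorm(3))
  })
  names(fs) <- roles
  structure(fs, class = "field_sample")
}

# Random map over random subsets of roles/components.
random_map <- function(omega0 = 1650) {
  comps <- c("potential", "field_x", "field_y", "field_z",
             "gradient_xx", "gradient_xy", "gradient_xz",
             "gradient_yy", "gradient_yz", "gradient_zz")
  roles <- sample(c("C", "O", "N", "H"), sample(1:4, 1))
  cf <- lapply(roles, function(r) {
    k <- sample(seq_along(comps), sample(1:10, 1))
    stats::setNames(rnorm(length(k), sd = 500), comps[k])
  })
  names(cf) <- roles
  electrostatic_map("rand", omega0, cf)
}

# Independent dot-product oracle for site_frequency.
site_frequency_oracle <- function(map, fs) {
  w <- map$gas_phase_frequency
  for (role in names(map$coefficients)) {
    cf <- map$coefficients[[role]]
    s <- fs[[role]]
    vals <- c(potential = s$potential,
              field_x = s$field[1], field_y = s$field[2],
              field_z = s$field[3],
              gradient_xx = s$gradient[1, 1], gradient_xy = s$gradient[1, 2],
              gradient_xz = s$gradient[1, 3], gradient_yy = s$gradient[2, 2],
              gradient_yz = s$gradient[2, 3], gradient_zz = s$gradient[3, 3])
    for (nm in names(cf)) w <- w + cf[[nm]] * vals[[nm]]
  }
  w
}

# Independent dihedral (praxeolitic formula), IUPAC convention.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(crossprod_vec(b1, v) * w)
  atan2(y, x) * 180 / pi
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix, independent of package internals.
rotation_matrix_test <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply a rigid rotation+translation to a frame.
transform_frame <- function(frame, R, shift = c(0, 0, 0)) {
  frame$xyz <- t(R %*% t(frame$xyz)) +
    matrix(shift, nrow(frame$xyz), 3, byrow = TRUE)
  frame
}

# Local maxima of a spectrum (interior strict maxima).
local_maxima <- function(sp) {
  y <- sp$intensity
  idx <- which(diff(sign(diff(y))) == -2) + 1
  idx[order(y[idx], decreasing = TRUE)]
}

# Two-state frequency-jump (telegraph) spectrum, symmetrized over the two
# initial states so the slow-exchange doublet has equal weights.
jump_spectrum <- function(tau_fs, nfr, cfg, delta = 8, omega0 = 1650,
                          step = 20) {
  p_flip <- 1 - exp(-step / tau_fs)
  s <- numeric(nfr); s[1] <- 1
  flips <- runif(nfr - 1) < p_flip
  for (k in 2:nfr) s[k] <- if (flips[k - 1]) -s[k - 1] else s[k - 1]
  spec_of <- function(sgn) {
    frames <- lapply(seq_len(nfr), function(k)
      mkframe(omega0 + sgn * delta * s[k]))
    absorption(propagate_response(frames, cfg), cfg)
  }
  a <- spec_of(1); b <- spec_of(-1)
  a$intensity <- (a$intensity + b$intensity) / 2
  a
}

# FWHM by linear interpolation of the half-maximum crossings.
fwhm <- function(sp) {
  y <- sp$intensity; x <- sp$wavenumber
  half <- max(y) / 2
  above <- which(y >= half)
  i1 <- min(above); i2 <- max(above)
  xl <- if (i1 > 1)
    approx(y[c(i1 - 1, i1)], x[c(i1 - 1, i1)], half)$y else x[i1]
  xr <- if (i2 < length(y))
    approx(y[c(i2, i2 + 1)], x[c(i2, i2 + 1)], half)$y else x[i2]
  xr - xl
}
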