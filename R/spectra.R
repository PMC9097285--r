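## Minimal time-domain linear-absorption calculator.
##
## Verifies Hamiltonian trajectories end-to-end: the first-order response is
## obtained by launching a one-exciton wavepacket with the transition dipole,
## propagating it under the time-ordered per-frame Hamiltonians (exact
## symmetric-matrix exponential per step), projecting back on the dipole,
## averaging over equidistant starting points, and damping by an exponential
## apodization representing the finite vibrational lifetime. The absorption
## spectrum is the real part of the half-sided Fourier transform on the
## requested window.

#' Linear-spectrum configuration
#'
#' @param window Spectral window, cm^-1 (default `c(1550, 1750)`).
#' @param t_max Maximum coherence time, fs (default 2560 = 2.56 ps).
#' @param step Coherence-time increment, fs (default 20).
#' @param lifetime Apodization lifetime T1, fs (default 1800 = 1.8 ps); the
#'   response is damped by `exp(-t / (2 T1))`.
#' @param n_starts Number of equidistant starting points (default 1000; the
#'   usable number is capped by the trajectory length).
#' @param resolution Output grid spacing, cm^-1 (default 1).
#' @param ref_freq Frequency recentring reference to avoid fast phase
#'   rotation, cm^-1 (default: window midpoint).
#' @return A `spectrum_config`.
#' @export
spectrum_config <- function(window = c(1550, 1750), t_max = 2560, step = 20,
                            lifetime = 1800, n_starts = 1000,
                            resolution = 1, ref_freq = mean(window)) {
  if (step <= 0) stop("step must be > 0")
  if (window[1] >= window[2]) stop("window must satisfy min < max")
  if (lifetime <= 0) stop("lifetime must be > 0")
  structure(list(window = window, t_max = t_max, step = step,
                 lifetime = lifetime, n_starts = n_starts,
                 resolution = resolution, ref_freq = ref_freq),
            class = "spectrum_config")
}

#' First-order response function of a Hamiltonian trajectory
#'
#' For each starting frame t0, the wavepacket `mu_alpha(t0)` is propagated by
#' the per-step unitary `exp(-i 2 pi c (H - ref) dt)` (eigendecomposition of
#' the symmetric single-frame Hamiltonian) and projected on
#' `mu_alpha(t0 + t)`; the three Cartesian components are summed, starts are
#' averaged, and the apodization `exp(-t/(2 T1))` applied. Frequencies are
#' recentred by `ref_freq`, so the response phase is relative to the
#' reference (accounted for in [absorption()]).
#'
#' @param frames List of `hamiltonian_frame`s with dipoles.
#' @param config [spectrum_config()].
#' @return Complex vector of length `t_max/step + 1`, with attributes `times`
#'   (fs) and `ref_freq`.
#' @export
propagate_response <- function(frames, config = spectrum_config()) {
  nt <- floor(config$t_max / config$step) + 1L
  nf <- length(frames)
  if (nf < nt)
    stop("trajectory too short: coherence window needs ", nt,
         " frames, trajectory has ", nf)
  n_starts <- max(1L, min(config$n_starts, nf - nt + 1L))
  starts <- unique(round(seq(1L, nf - nt + 1L, length.out = n_starts)))
  n <- length(frames[[1]]$omega)
  phase <- 2 * pi * .const$c_cm_fs * config$step
  ## per-frame propagators (cache: each frame's U is reused across starts)
  U <- vector("list", nf)
  propagator <- function(f) {
    H <- f$J
    diag(H) <- f$omega - config$ref_freq
    e <- eigen(H, symmetric = TRUE)
    e$vectors %*% (exp(-1i * phase * e$values) * t(e$vectors))
  }
  resp <- complex(nt)
  for (s in starts) {
    psi <- frames[[s]]$dipoles + 0i          # N x 3: three launches at once
    resp[1] <- resp[1] + sum(frames[[s]]$dipoles * Re(psi))
    for (k in seq_len(nt - 1L)) {
      fidx <- s + k - 1L
      if (is.null(U[[fidx]])) U[[fidx]] <- propagator(frames[[fidx]])
      psi <- U[[fidx]] %*% psi
      resp[k + 1L] <- resp[k + 1L] + sum(frames[[s + k]]$dipoles * psi)
    }
  }
  resp <- resp / length(starts)
  times <- (seq_len(nt) - 1L) * config$step
  resp <- resp * exp(-times / (2 * config$lifetime))
  structure(resp, times = times, ref_freq = config$ref_freq)
}

#' Absorption spectrum from a response function
#'
#' Real part of the half-sided Fourier transform of the response on the
#' window grid (trapezoidal quadrature), with the recentring reference of
#' [propagate_response()] undone.
#'
#' @param response Output of [propagate_response()].
#' @param config [spectrum_config()].
#' @return data.frame with `wavenumber` (cm^-1) and `intensity` (arbitrary
#'   units).
#' @export
absorption <- function(response, config = spectrum_config()) {
  times <- attr(response, "times")
  ref <- attr(response, "ref_freq")
  grid <- seq(config$window[1], config$window[2], by = config$resolution)
  w <- rep(config$step, length(times))
  w[c(1, length(w))] <- config$step / 2
  ph <- outer(grid - ref, times, function(om, t)
    2 * pi * .const$c_cm_fs * om * t)
  intensity <- as.numeric(Re(exp(1i * ph) %*% (w * as.complex(response))))
  data.frame(wavenumber = grid, intensity = intensity)
}

#' Rigid shift maximizing the overlap of two spectra
#'
#' Scans shifts of the simulated spectrum at grid resolution, maximizing the
#' inner product of the unit-normalized spectra, then refines by parabolic
#' interpolation of the objective around the best grid shift. The returned
#' value is the shift to ADD to the simulated spectrum's frequency axis for
#' best agreement with the reference (positive = simulation sits to the red
#' of the reference).
#'
#' @param sim,ref data.frames with `wavenumber`, `intensity` on commensurate
#'   grids.
#' @param search Shift scan range, cm^-1 (default `c(-60, 60)`).
#' @return Shift, cm^-1.
#' @export
overlap_shift <- function(sim, ref, search = c(-60, 60)) {
  dg <- stats::median(diff(ref$wavenumber))
  shifts <- seq(search[1], search[2], by = dg)
  score <- vapply(shifts, function(s) {
    si <- stats::approx(sim$wavenumber + s, sim$intensity, ref$wavenumber,
                        rule = 1)$y
    keep <- !is.na(si)
    if (sum(keep) < 3 || all(si[keep] == 0)) return(NA_real_)
    a <- si[keep]; b <- ref$intensity[keep]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, 0)
  if (all(is.na(score)))
    stop("no overlap between the spectra anywhere in the scan range")
  k <- which.max(score)
  best <- shifts[k]
  if (k > 1 && k < length(shifts) &&
      !any(is.na(score[(k - 1):(k + 1)]))) {
    y1 <- score[k - 1]; y2 <- score[k]; y3 <- score[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps)
      best <- best + dg * 0.5 * (y1 - y3) / den
  }
  best
}
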