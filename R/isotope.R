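## Isotope-label postprocessing of Hamiltonian trajectories.
##
## 13C labelling shifts an amide-I site by about -41 cm^-1 and combined
## 13C18O labelling by about -66 cm^-1; these empirical shifts are the
## default mode. A reduced-mass scaling mode (harmonic-oscillator formula on
## the C=O diatomic) is offered for sensitivity checks. Labelled subsets can
## be truncated out of the Hamiltonian for efficient label-spectrum
## calculations.

.label_defaults <- c(C13 = -41, C13O18 = -66)

## C=O reduced masses (amu) for the mass-scaling mode.
.red_mass <- function(mC, mO) mC * mO / (mC + mO)
.mass_factors <- c(
  C13 = sqrt(.red_mass(12, 15.994915) / .red_mass(13.003355, 15.994915)),
  C13O18 = sqrt(.red_mass(12, 15.994915) / .red_mass(13.003355, 17.999160))
)

#' Isotope labelling specification
#'
#' @param sites 0-based unit ids of the labelled sites.
#' @param type `"C13"`, `"C13O18"` or `"custom"`.
#' @param shift Shift in cm^-1; defaults -41 for C13 and -66 for C13O18,
#'   required for `"custom"`.
#' @param mode `"shift"` (default; apply the empirical shift) or
#'   `"mass_scaling"` (harmonic-oscillator reduced-mass scaling of the C=O
#'   oscillator; unavailable for `"custom"`).
#' @return A `label_spec`.
#' @export
label_spec <- function(sites, type = c("C13", "C13O18", "custom"),
                       shift = NULL, mode = c("shift", "mass_scaling")) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("labelled sites must be distinct")
  if (is.null(shift)) {
    if (type == "custom") stop("custom labels need an explicit shift")
    shift <- unname(.label_defaults[type])
  }
  if (!is.finite(shift)) stop("label shift must be finite")
  if (mode == "mass_scaling" && type == "custom")
    stop("mass scaling is only defined for C13 and C13O18 labels")
  structure(list(sites = sites, type = type, shift = shift, mode = mode),
            class = "label_spec")
}

#' Read a label file
#'
#' One site per line: `unit_id label_type [shift]`; `#` comments.
#' All sites must share one label type/shift (one spec per file).
#'
#' @param path File.
#' @return A `label_spec`.
#' @export
read_label_file <- function(path) {
  lines <- trimws(sub("#.*", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty label file: ", path)
  parts <- strsplit(lines, "\\s+")
  sites <- as.integer(vapply(parts, `[`, "", 1L))
  types <- vapply(parts, `[`, "", 2L)
  shifts <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 3) p[3] else NA_character_, "")))
  if (length(unique(types)) != 1L)
    stop("label file mixes label types; use one file per label scheme")
  sh <- shifts[!is.na(shifts)]
  label_spec(sites, types[1],
             shift = if (length(sh)) sh[1] else NULL)
}

.check_sites <- function(spec, n) {
  if (any(spec$sites < 0L | spec$sites >= n))
    stop("labelled site id(s) out of range [0, ", n - 1, "]: ",
         paste(spec$sites[spec$sites < 0L | spec$sites >= n], collapse = ", "))
}

#' Apply isotope labels to a Hamiltonian frame
#'
#' Shift mode adds the label shift to the labelled site frequencies;
#' mass-scaling mode multiplies them by the reduced-mass ratio
#' \eqn{\sqrt{\mu_{unlabeled}/\mu_{labeled}}} of the C=O oscillator.
#' Couplings, dipoles and positions are unchanged.
#'
#' @param frame `hamiltonian_frame`.
#' @param spec [label_spec()].
#' @return Modified `hamiltonian_frame`.
#' @export
apply_labels <- function(frame, spec) {
  n <- length(frame$omega)
  .check_sites(spec, n)
  idx <- spec$sites + 1L
  if (spec$mode == "shift") {
    frame$omega[idx] <- frame$omega[idx] + spec$shift
  } else {
    frame$omega[idx] <- frame$omega[idx] * .mass_factors[[spec$type]]
  }
  frame
}

#' Truncate a Hamiltonian frame to the labelled sites
#'
#' Keeps the labelled rows/columns of frequencies, couplings, dipoles and
#' positions in their original relative order; the common approximation that
#' labelled units decouple from the unlabelled ones.
#'
#' @param frame `hamiltonian_frame`.
#' @param spec [label_spec()] with at least one site.
#' @return Reduced `hamiltonian_frame` of dimension `length(spec$sites)`.
#' @export
truncate_to_labels <- function(frame, spec) {
  if (!length(spec$sites)) stop("cannot truncate to an empty label set")
  n <- length(frame$omega)
  .check_sites(spec, n)
  idx <- sort(spec$sites) + 1L
  frame$omega <- frame$omega[idx]
  frame$J <- frame$J[idx, idx, drop = FALSE]
  if (!is.null(frame$anharmonicity))
    frame$anharmonicity <- frame$anharmonicity[idx]
  if (!is.null(frame$dipoles))
    frame$dipoles <- frame$dipoles[idx, , drop = FALSE]
  if (!is.null(frame$positions))
    frame$positions <- frame$positions[idx, , drop = FALSE]
  frame
}
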