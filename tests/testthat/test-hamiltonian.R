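# Frame assembly, trajectory file formats, end-to-end pipeline runs.

test_that("a one-unit system with no charges sits at the gas-phase frequency", {
  fx <- make_peptide(fixture_spec("ideal_helix", n_residues = 2))
  top <- fx$topology
  top$atoms$charge <- 0
  u <- detect_amide_units(top)
  m <- test_map(omega0 = 1650)
  hf <- build_frame(fx$frames[[1]], top, u, m)
  expect_equal(hf$omega, 1650)
  expect_equal(hf$J, matrix(0, 1, 1))
  expect_equal(hf$anharmonicity, 16)
  expect_equal(nrow(hf$dipoles), 1)
})

test_that("build_frame composes the four submodule results", {
  fx <- make_peptide(fixture_spec("fluctuating", n_residues = 3,
                                  n_charges = 25, seed = 41))
  top <- fx$topology
  u <- detect_amide_units(top)
  fr <- fx$frames[[1]]
  m <- test_map()
  set.seed(42)
  grids <- list(shift_prev = rama_grid(matrix(rnorm(144), 12, 12), 30,
                                       "shift_prev"),
                shift_next = rama_grid(matrix(rnorm(144), 12, 12), 30,
                                       "shift_next"),
                coupling = rama_grid(matrix(rnorm(144), 12, 12), 30,
                                     "coupling"))
  cfg <- pipeline_config()
  hf <- build_frame(fr, top, u, m, grids, cfg)
  # hand-compose per unit: electrostatics -> local frame -> map -> NN shift
  for (i in seq_along(u)) {
    fs <- field_at_unit(fr, u[[i]], top$atoms$charge, cfg$map_cutoff,
                        exclusions = amidemap:::default_exclusions(
                          u[[i]], top, u))
    xyz <- fr$xyz
    R <- amidemap:::amide_frame(xyz[u[[i]]$atoms["C"], ],
                                xyz[u[[i]]$atoms["O"], ],
                                xyz[u[[i]]$atoms["N"], ])
    w <- site_frequency(m, amidemap:::rotate_field_sample(fs, R)) +
      nn_frequency_shift(u[[i]], top, u, fr, grids)
    expect_equal(hf$omega[i], w, tolerance = 1e-12)
    d <- site_dipole(m, u[[i]], fr)
    expect_equal(hf$dipoles[i, ], d$mu, tolerance = 1e-12)
    expect_equal(hf$positions[i, ], d$position, tolerance = 1e-12)
  }
  dip <- lapply(u, function(x) site_dipole(m, x, fr))
  expect_equal(hf$J, assemble_couplings(fr, top, u, dip, cfg$coupling,
                                        grids, m))
  # eigenvalues of the symmetric one-exciton matrix are real
  M <- hf$J; diag(M) <- hf$omega
  expect_true(all(abs(Im(eigen(M)$values)) == 0))
})

test_that("frame frequencies are invariant under rigid rotation of the system", {
  fx <- make_peptide(fixture_spec("fluctuating", n_residues = 3,
                                  n_charges = 20, seed = 43))
  top <- fx$topology
  u <- detect_amide_units(top)
  fr <- fx$frames[[1]]
  fr$box <- NULL
  m <- test_map()
  h1 <- build_frame(fr, top, u, m)
  fr2 <- transform_frame(fr, rotation_matrix_test(c(0, 1, 1), 35))
  h2 <- build_frame(fr2, top, u, m)
  expect_equal(h2$omega, h1$omega, tolerance = 1e-8)
  expect_equal(h2$J, h1$J, tolerance = 1e-8)
})

test_that("class handling: direct side-chain map versus class shift", {
  res <- c("ALA", "ASN", "ALA", "PRO", "ALA")
  fx <- make_peptide(fixture_spec("ideal_sheet_dimer", n_residues = 5,
                                  residues = res))
  top <- fx$topology
  top$atoms$charge <- 0   # identical (null) environment for every unit
  u <- detect_amide_units(top)
  m <- test_map(omega0 = 1650)
  hf <- build_frame(fx$frames[[1]], top, u, m)
  cls <- vapply(u, `[[`, "", "amide_class")
  expect_equal(unname(hf$omega[cls == "secondary"]),
               rep(1650, sum(cls == "secondary")))
  expect_equal(unname(hf$omega[cls == "tertiary_preproline"]),
               rep(1650 - 27, sum(cls == "tertiary_preproline")))
  expect_equal(unname(hf$omega[cls == "primary_sidechain"]),
               rep(1650 + 30, sum(cls == "primary_sidechain")))
  # with a class-specific side-chain map, that map is used unshifted
  msc <- electrostatic_map("sc", 1700, list(O = c(potential = 1)),
                           classes = "primary_sidechain")
  hf2 <- build_frame(fx$frames[[1]], top, u,
                     list(secondary = m, primary_sidechain = msc))
  expect_equal(unname(hf2$omega[cls == "primary_sidechain"]),
               rep(1700, sum(cls == "primary_sidechain")))
  expect_equal(unname(hf2$omega[cls == "secondary"]),
               rep(1650, sum(cls == "secondary")))
})

test_that("a trypsin-inhibitor-like fixture gives a 61-dimensional Hamiltonian", {
  res <- rep("ALA", 58)
  res[c(2, 8, 9, 13)] <- "PRO"
  res[c(24, 43, 44)] <- "ASN"
  res[31] <- "GLN"
  fx <- make_peptide(fixture_spec("ideal_helix", n_residues = 58,
                                  residues = res))
  u <- detect_amide_units(fx$topology)
  m <- test_map()
  hf <- build_frame(fx$frames[[1]], fx$topology, u, m,
                    config = pipeline_config(
                      coupling = coupling_config(prune_threshold = 0)))
  expect_length(hf$omega, 61)
  expect_identical(dim(hf$J), c(61L, 61L))
  # side chains occupy the last four indices
  cls <- vapply(u, `[[`, "", "amide_class")
  expect_identical(which(cls == "primary_sidechain"), 58:61)
})

test_that("Hamiltonian files round-trip in binary and text with the stated size", {
  f1 <- mkframe(c(1650, 1660), matrix(c(0, 5, 5, 0), 2), t = 0)
  f2 <- mkframe(c(1652, 1658), matrix(c(0, 4, 4, 0), 2), t = 20)
  pb <- tempfile(fileext = ".bin")
  write_hamiltonian(list(f1, f2), pb, "binary")
  # 4 bytes x (1 + N(N+1)/2) per frame
  expect_identical(file.info(pb)$size, 2 * 4 * (1 + 3))
  back <- read_hamiltonian(pb, 2, "binary")
  expect_length(back, 2)
  expect_equal(back[[1]]$omega, c(1650, 1660), tolerance = 1e-6)
  expect_equal(back[[1]]$J[1, 2], 5, tolerance = 1e-6)
  expect_equal(back[[2]]$time, 20, tolerance = 1e-6)
  expect_equal(back[[2]]$J, t(back[[2]]$J))
  # text mirrors binary within single precision
  pt <- tempfile(fileext = ".txt")
  write_hamiltonian(list(f1, f2), pt, "text")
  backt <- read_hamiltonian(pt, 2, "text")
  for (k in 1:2) {
    expect_equal(backt[[k]]$omega, back[[k]]$omega, tolerance = 1e-6)
    expect_equal(backt[[k]]$J, back[[k]]$J, tolerance = 1e-6)
  }
  # inconsistent site counts across frames are rejected
  f3 <- mkframe(c(1650, 1660, 1670))
  expect_error(write_hamiltonian(list(f1, f3), tempfile()), "inconsistent")
})

test_that("vector files round-trip with the component-major layout", {
  set.seed(44)
  frames <- lapply(0:2, function(k)
    mkframe(c(1650, 1655, 1660), mu = matrix(rnorm(9), 3, 3),
            pos = matrix(runif(9), 3, 3), t = 20 * k))
  p <- tempfile(fileext = ".bin")
  write_vectors(frames, p, "dipoles")
  expect_identical(file.info(p)$size, 3 * 4 * (1 + 3 * 3))
  back <- read_vectors(p, 3)
  for (k in 1:3)
    expect_equal(back[[k]]$xyz, frames[[k]]$dipoles, tolerance = 1e-6)
  # component-major on disk: floats 2..4 of frame 1 are the x components
  con <- file(p, "rb")
  raw <- readBin(con, numeric(), n = 10, size = 4)
  close(con)
  expect_equal(raw[2:4], frames[[1]]$dipoles[, 1], tolerance = 1e-6)
  # text mirror
  pt <- tempfile(fileext = ".txt")
  write_vectors(frames, pt, "positions", "text")
  backt <- read_vectors(pt, 3, "text")
  for (k in 1:3)
    expect_equal(backt[[k]]$xyz, frames[[k]]$positions, tolerance = 1e-6)
})

test_that("the pipeline is deterministic, streams, and honours stride", {
  dirn <- tempfile(); dir.create(dirn)
  fx <- make_peptide(fixture_spec("fluctuating", n_residues = 4,
                                  n_charges = 30, seed = 45, n_frames = 10))
  paths <- write_fixture(fx, dirn, "run")
  m <- test_map()
  grids <- demo_map_set()$grids
  out1 <- run_pipeline(paths$topology, paths$trajectory, paths$charges,
                       m, grids, out_prefix = file.path(dirn, "a"))
  out2 <- run_pipeline(paths$topology, paths$trajectory, paths$charges,
                       m, grids, out_prefix = file.path(dirn, "b"))
  # byte-identical outputs on identical inputs
  for (nm in c("hamiltonian", "dipoles", "positions")) {
    expect_identical(readBin(out1$paths[[nm]], "raw",
                             file.info(out1$paths[[nm]])$size),
                     readBin(out2$paths[[nm]], "raw",
                             file.info(out2$paths[[nm]])$size))
  }
  expect_identical(out1$n_frames, 10L)
  hs <- read_hamiltonian(out1$paths$hamiltonian, out1$n_sites)
  expect_length(hs, 10)
  # frames match direct construction (streamed path = in-memory path)
  u <- detect_amide_units(read_topology(paths$topology, paths$charges))
  expect_identical(length(u), out1$n_sites)
  # time stamps follow the trajectory
  expect_equal(vapply(hs, `[[`, 0, "time"), seq(0, 180, by = 20),
               tolerance = 1e-4)
  # stride halves the frame count
  out3 <- run_pipeline(paths$topology, paths$trajectory, paths$charges,
                       m, grids, out_prefix = file.path(dirn, "c"),
                       stride = 2L)
  expect_identical(out3$n_frames, 5L)
  # run report summarizes the setup
  rep <- readLines(out1$paths$report)
  expect_true(any(grepl("anharmonicity: 16", rep)))
  expect_true(any(grepl("units \\(3\\)", rep)))
})

test_that("the streaming GRO reader yields the same frames as read_gro", {
  dirn <- tempfile(); dir.create(dirn)
  fx <- make_peptide(fixture_spec("fluctuating", n_residues = 3,
                                  n_charges = 10, seed = 46, n_frames = 4))
  paths <- write_fixture(fx, dirn, "s")
  all_at_once <- read_gro(paths$trajectory)$frames
  rd <- gro_frame_reader(paths$trajectory)
  k <- 0L
  repeat {
    fr <- rd()
    if (is.null(fr)) break
    k <- k + 1L
    expect_equal(fr$xyz, all_at_once[[k]]$xyz)
    expect_equal(fr$box, all_at_once[[k]]$box)
  }
  expect_identical(k, 4L)
})
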