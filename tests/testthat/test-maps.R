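# Frequency maps: linear form, bilinear periodic lookup, class shifts,
# dipole construction, YAML round trips.

test_that("site_frequency is the declared linear form", {
  m0 <- electrostatic_map("zero", 1700,
                          coefficients = list(O = c(potential = 100)))
  fs <- random_field_sample()
  fs$O$potential <- 0.01
  expect_equal(site_frequency(m0, fs), 1701)
  # zero field sample returns omega0 exactly
  z <- lapply(c("C", "O", "N", "H"), function(r)
    list(potential = 0, field = numeric(3), gradient = matrix(0, 3, 3),
         position = numeric(3)))
  names(z) <- c("C", "O", "N", "H")
  expect_identical(site_frequency(m0, z), 1700)

  set.seed(21)
  for (k in 1:100) {
    m <- random_map()
    fs <- random_field_sample()
    expect_equal(site_frequency(m, fs), site_frequency_oracle(m, fs),
                 tolerance = 1e-10)
  }
})

test_that("maps consume only the components they declare", {
  m <- electrostatic_map("potential-only", 1650,
                         coefficients = list(O = c(potential = 500)))
  set.seed(22)
  fs1 <- random_field_sample()
  fs2 <- fs1
  fs2$O$field <- fs2$O$field + 100
  fs2$O$gradient <- fs2$O$gradient + 100
  fs2$C$potential <- fs2$C$potential + 100
  expect_equal(site_frequency(m, fs1), site_frequency(m, fs2))
})

test_that("site_frequency is linear in the field sample", {
  set.seed(23)
  m <- random_map(1650)
  f1 <- random_field_sample()
  f2 <- random_field_sample()
  mix <- function(a, b) {
    out <- f1
    for (r in names(out)) {
      out[[r]]$potential <- a * f1[[r]]$potential + b * f2[[r]]$potential
      out[[r]]$field <- a * f1[[r]]$field + b * f2[[r]]$field
      out[[r]]$gradient <- a * f1[[r]]$gradient + b * f2[[r]]$gradient
    }
    out
  }
  a <- 0.3; b <- -1.7
  w0 <- m$gas_phase_frequency
  expect_equal(site_frequency(m, mix(a, b)) - w0,
               a * (site_frequency(m, f1) - w0) +
                 b * (site_frequency(m, f2) - w0),
               tolerance = 1e-9)
})

test_that("a map requiring H data rejects tertiary units", {
  m <- electrostatic_map("needs-H", 1650,
                         coefficients = list(H = c(potential = 50)))
  fs <- random_field_sample(roles = c("C", "O", "N"))  # no H present
  expect_error(site_frequency(m, fs), "tertiary")
})

test_that("nn_lookup reproduces nodes, cell centers and the periodic seam", {
  set.seed(24)
  V <- matrix(rnorm(144), 12, 12)
  g <- rama_grid(V, 30, "coupling")
  nodes <- seq(-180, 150, by = 30)
  for (k in 1:20) {
    i <- sample(12, 1); j <- sample(12, 1)
    expect_equal(nn_lookup(g, nodes[i], nodes[j]), V[i, j])
  }
  # center of a cell: mean of the four corners
  expect_equal(nn_lookup(g, -165, -165), mean(V[1:2, 1:2]))
  # wrap: node at 180 equals node at -180
  expect_equal(nn_lookup(g, 180, 0), nn_lookup(g, -180, 0))
  # tiling oracle: tile the table 3x3 and interpolate in the middle copy
  tile <- rbind(cbind(V, V, V), cbind(V, V, V), cbind(V, V, V))
  tiled_lookup <- function(phi, psi) {
    u <- (phi + 180 + 360) / 30
    v <- (psi + 180 + 360) / 30
    i0 <- floor(u); j0 <- floor(v)
    fu <- u - i0; fv <- v - j0
    (1 - fu) * (1 - fv) * tile[i0 + 1, j0 + 1] +
      fu * (1 - fv) * tile[i0 + 2, j0 + 1] +
      (1 - fu) * fv * tile[i0 + 1, j0 + 2] +
      fu * fv * tile[i0 + 2, j0 + 2]
  }
  expect_equal(nn_lookup(g, 179, 0), tiled_lookup(179, 0), tolerance = 1e-12)
  for (k in 1:200) {
    phi <- runif(1, -180, 180); psi <- runif(1, -180, 180)
    expect_equal(nn_lookup(g, phi, psi), tiled_lookup(phi, psi),
                 tolerance = 1e-12)
  }
})

test_that("nn_lookup is continuous across cell boundaries and the seam", {
  set.seed(25)
  g <- rama_grid(matrix(rnorm(144), 12, 12), 30, "shift_prev")
  rng <- diff(range(g$values))
  eps <- 1e-11
  for (edge in c(-180, -150, 0, 150, 180)) {
    for (psi in runif(5, -180, 180)) {
      jump <- abs(nn_lookup(g, edge - eps, psi) -
                    nn_lookup(g, edge + eps, psi))
      expect_lt(jump, 1e-9 * rng)
      jump2 <- abs(nn_lookup(g, psi, edge - eps) -
                     nn_lookup(g, psi, edge + eps))
      expect_lt(jump2, 1e-9 * rng)
    }
  }
})

test_that("nn_frequency_shift composes the two neighbour lookups", {
  fx <- make_peptide(fixture_spec("ideal_helix", n_residues = 6))
  u <- detect_amide_units(fx$topology)
  gp <- rama_grid(matrix(2.5, 12, 12), 30, "shift_prev")
  gn <- rama_grid(matrix(1.25, 12, 12), 30, "shift_next")
  grids <- list(shift_prev = gp, shift_next = gn)
  # interior unit: both neighbours present, constant grids add up
  expect_equal(nn_frequency_shift(u[[3]], fx$topology, u, fx$frames[[1]],
                                  grids), 3.75)
  # terminal units miss one side
  expect_equal(nn_frequency_shift(u[[1]], fx$topology, u, fx$frames[[1]],
                                  grids), 2.5)
  expect_equal(nn_frequency_shift(u[[5]], fx$topology, u, fx$frames[[1]],
                                  grids), 1.25)
  # random grids: match explicit composition of nn_lookup calls
  set.seed(26)
  g1 <- rama_grid(matrix(rnorm(144), 12, 12), 30, "shift_prev")
  g2 <- rama_grid(matrix(rnorm(144), 12, 12), 30, "shift_next")
  ra <- ramachandran_angles(u[[3]], fx$topology, u, fx$frames[[1]])
  expect_equal(
    nn_frequency_shift(u[[3]], fx$topology, u, fx$frames[[1]],
                       list(shift_prev = g1, shift_next = g2)),
    unname(nn_lookup(g1, ra$`next`["phi"], ra$`next`["psi"]) +
             nn_lookup(g2, ra$prev["phi"], ra$prev["psi"])),
    tolerance = 1e-12)
})

test_that("class shifts apply the documented red/blue shifts", {
  expect_equal(class_shift(1650, "tertiary_preproline"), 1623)
  expect_equal(class_shift(1650, "primary_sidechain"), 1680)
  expect_equal(class_shift(1650, "secondary"), 1650)
  # idempotent identity on secondary
  expect_equal(class_shift(class_shift(1650, "secondary"), "secondary"), 1650)
  # user-configurable
  expect_equal(class_shift(1650, "tertiary_preproline",
                           preproline_shift = 20), 1630)
  expect_equal(class_shift(1650, "primary_sidechain",
                           sidechain_shift = 12), 1662)
})

test_that("site_dipole follows the in-plane construction and is equivariant", {
  fx <- make_peptide(fixture_spec("ideal_helix", n_residues = 3))
  u <- detect_amide_units(fx$topology)
  fr <- fx$frames[[1]]
  xyz <- fr$xyz
  rC <- xyz[u[[1]]$atoms["C"], ]; rO <- xyz[u[[1]]$atoms["O"], ]
  rN <- xyz[u[[1]]$atoms["N"], ]
  # 0 degrees, no offset: parallel to C->O, positioned at C
  m0 <- electrostatic_map("m0", 1650, list(O = c(potential = 1)),
                          dipole = list(magnitude = 2, angle = 0, offset = 0))
  d0 <- site_dipole(m0, u[[1]], fr)
  eCO <- (rO - rC) / sqrt(sum((rO - rC)^2))
  expect_equal(d0$mu, 2 * eCO, tolerance = 1e-12)
  expect_equal(d0$origin, rC, tolerance = 1e-12)
  expect_equal(d0$position, rC)
  # 20 degrees: Gram-Schmidt oracle in the O=C-N plane
  m20 <- electrostatic_map("m20", 1650, list(O = c(potential = 1)),
                           dipole = list(magnitude = 0.37, angle = 20,
                                         offset = 0.01))
  d20 <- site_dipole(m20, u[[1]], fr)
  e1 <- eCO
  v <- (rN - rC) - sum((rN - rC) * e1) * e1
  e2 <- v / sqrt(sum(v^2))
  oracle <- 0.37 * (cos(20 * pi / 180) * e1 + sin(20 * pi / 180) * e2)
  expect_equal(d20$mu, oracle, tolerance = 1e-10)
  expect_equal(d20$origin, rC + 0.01 * e1, tolerance = 1e-12)
  # equivariance under rigid rotation
  R <- rotation_matrix_test(c(2, -1, 1), 90)
  fr2 <- transform_frame(fr, R, c(1, 2, 3))
  d20r <- site_dipole(m20, u[[1]], fr2)
  expect_equal(d20r$mu, as.numeric(R %*% d20$mu), tolerance = 1e-10)
  expect_equal(d20r$origin, as.numeric(R %*% d20$origin) + c(1, 2, 3),
               tolerance = 1e-10)
  # collinear C, O, N is an error
  fr3 <- fr
  fr3$xyz[u[[1]]$atoms["N"], ] <- rC + 2 * (rO - rC)
  expect_error(site_dipole(m20, u[[1]], fr3), "collinear")
})

test_that("map and grid files round-trip through YAML", {
  m <- test_map()
  p <- tempfile(fileext = ".yaml")
  write_map(m, p)
  m2 <- load_map(p)
  expect_equal(m2$gas_phase_frequency, m$gas_phase_frequency)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$dipole$magnitude, m$dipole$magnitude)
  expect_equal(m2$transition_charges, m$transition_charges)

  set.seed(27)
  g <- rama_grid(matrix(rnorm(144), 12, 12), 30, "coupling")
  pg <- tempfile(fileext = ".yaml")
  write_map(g, pg)
  g2 <- load_map(pg)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_identical(g2$payload, "coupling")

  # non-rectangular grid file names the offending row
  doc <- yaml::read_yaml(pg)
  doc$values[[3]] <- doc$values[[3]][-1]
  pb <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, pb)
  expect_error(load_map(pb), "rectangular")
  # missing gas-phase frequency
  pm <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(kind = "electrostatic_map", name = "x",
                        coefficients = list(O = list(potential = 1))), pm)
  expect_error(load_map(pm), "gas_phase_frequency")
})

test_that("the shipped demo map set loads and is self-consistent", {
  set <- demo_map_set()
  expect_s3_class(set$maps$secondary, "electrostatic_map")
  expect_s3_class(set$grids$coupling, "rama_grid")
  expect_identical(set$maps$primary_sidechain$classes, "primary_sidechain")
  expect_equal(sum(set$maps$secondary$transition_charges), 0,
               tolerance = 1e-6)
})
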