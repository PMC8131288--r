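# Restraint potentials, effective distances, tensors and violations.

res_d <- list(r0 = 0.20, r1 = 0.30, r2 = 0.40)

test_that("flat-bottom distance energy matches hand evaluation", {
  expect_equal(distance_energy(0.25, res_d, 1000), 0)
  expect_equal(distance_energy(0.35, res_d, 1000), 0.5 * 1000 * 0.05^2)
  # linear branch: 1/2 k (r2-r1)(2r - r2 - r1)
  expect_equal(distance_energy(0.50, res_d, 1000),
               0.5 * 1000 * 0.1 * (1.0 - 0.4 - 0.3))
  expect_equal(distance_energy(0.50, res_d, 1000), 15)
  # below the lower bound
  expect_equal(distance_energy(0.15, res_d, 1000), 0.5 * 1000 * 0.05^2)
})

test_that("distance energy is continuous at r0, r1 and r2", {
  eps <- 1e-9
  for (edge in c(res_d$r0, res_d$r1, res_d$r2)) {
    lo <- distance_energy(edge - eps, res_d, 1000)
    hi <- distance_energy(edge + eps, res_d, 1000)
    expect_lt(abs(hi - lo), 1e-5)
  }
})

test_that("the linear branch takes the quadratic value at r2", {
  for (k in c(1, 250, 1000)) {
    quad_limit <- 0.5 * k * (res_d$r2 - res_d$r1)^2
    expect_equal(distance_energy(res_d$r2, res_d, k), quad_limit)
  }
})

test_that("r^-6 effective distances obey their bounds", {
  expect_equal(effective_distance(rep(0.37, 9)), 0.37)
  expect_equal(effective_distance(c(0.3, 0.6)),
               ((0.3^-6 + 0.6^-6) / 2)^(-1 / 6))
  set.seed(3)
  for (i in 1:25) {
    d <- runif(sample(2:9, 1), 0.15, 1.2)
    m <- effective_distance(d, "mean")
    s <- effective_distance(d, "sum")
    expect_true(m >= min(d) - 1e-12 && m <= max(d) + 1e-12)
    expect_lte(s, min(d) + 1e-12)
    expect_lte(s, m)
  }
  expect_error(effective_distance(numeric(0)), "empty")
})

test_that("dihedral energy is flat in the well and harmonic outside", {
  res <- list(phi0 = -70, dphi = 30)
  expect_equal(dihedral_energy(-70, res, 1000), 0)
  expect_equal(dihedral_energy(-80, res, 1000), 0)
  expect_equal(dihedral_energy(-100, res, 1000), 0)   # well edge
  expect_equal(dihedral_energy(-110, res, 1000),
               0.5 * 1000 * (10 * pi / 180)^2)
  expect_equal(dihedral_energy(-110, res, 1000), 15.23, tolerance = 1e-3)
})

test_that("dihedral energy is periodic in 360 degrees", {
  set.seed(8)
  for (i in 1:30) {
    res <- list(phi0 = runif(1, -180, 180), dphi = runif(1, 0, 60))
    phi <- runif(1, -360, 360)
    e <- dihedral_energy(phi, res, 1000)
    expect_equal(dihedral_energy(phi + 360, res, 1000), e)
    expect_equal(dihedral_energy(phi - 720, res, 1000), e)
  }
  # continuity at the well edges
  res <- list(phi0 = 40, dphi = 25)
  for (edge in c(40 - 25, 40 + 25)) {
    expect_lt(abs(dihedral_energy(edge + 1e-7, res, 1000) -
                    dihedral_energy(edge - 1e-7, res, 1000)), 1e-8)
  }
})

make_rdc_set <- function(n, comp, seed = 1, const = 6.083) {
  set.seed(seed)
  xyz <- matrix(0, 2 * n, 3)
  A <- matrix(c(comp[1], comp[3], comp[4],
                comp[3], comp[2], comp[5],
                comp[4], comp[5], -comp[1] - comp[2]), 3, 3)
  restraints <- vector("list", n)
  for (k in seq_len(n)) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    xyz[2 * k - 1, ] <- rnorm(3)
    xyz[2 * k, ] <- xyz[2 * k - 1, ] + 0.1 * v
    obs <- const * as.numeric(t(v) %*% A %*% v)
    restraints[[k]] <- list(atoms = c(2 * k - 1, 2 * k), experiment = 1L,
                            label = k, alpha = 3, const = const,
                            obs = obs, weight = 1)
  }
  list(xyz = xyz, restraints = restraints, A = A)
}

test_that("the alignment tensor is recovered exactly from noiseless RDCs", {
  comp <- c(2e-4, -1.5e-4, 8e-5, -6e-5, 1.2e-4)
  s <- make_rdc_set(20, comp, seed = 2)
  fit <- fit_alignment_tensor(s$xyz, s$restraints)
  expect_false(fit$underdetermined)
  expect_lt(max(abs(fit$components - comp)) / max(abs(comp)), 1e-8)
  # exact symmetry and zero trace
  expect_identical(fit$A, t(fit$A))
  expect_equal(sum(diag(fit$A)), 0)
  # back-calculation reproduces the observations
  calc <- back_calculate_rdc(fit, s$xyz, s$restraints)
  expect_equal(calc, vapply(s$restraints, function(r) r$obs, 1),
               tolerance = 1e-10)
})

test_that("degenerate tensor fits are flagged, zero data gives zero tensor", {
  s <- make_rdc_set(20, c(2e-4, -1e-4, 5e-5, 0, 0), seed = 3)
  for (r in seq_along(s$restraints)) s$restraints[[r]]$obs <- 0
  fit0 <- fit_alignment_tensor(s$xyz, s$restraints)
  expect_equal(fit0$A, matrix(0, 3, 3))
  s4 <- make_rdc_set(4, c(2e-4, -1e-4, 5e-5, 0, 0), seed = 4)
  fit4 <- fit_alignment_tensor(s4$xyz, s4$restraints)
  expect_true(fit4$underdetermined)
})

test_that("least-squares residuals are orthogonal to the design", {
  comp <- c(2e-4, -1.5e-4, 8e-5, -6e-5, 1.2e-4)
  s <- make_rdc_set(15, comp, seed = 6)
  set.seed(7)
  for (r in seq_along(s$restraints))
    s$restraints[[r]]$obs <- s$restraints[[r]]$obs + rnorm(1, sd = 0.1)
  fit <- fit_alignment_tensor(s$xyz, s$restraints)
  resid <- vapply(s$restraints, function(r) r$obs, 1) - fit$fitted
  refit <- fit_alignment_tensor(s$xyz, {
    rr <- s$restraints
    for (k in seq_along(rr)) rr[[k]]$obs <- resid[k]
    rr
  })
  expect_lt(max(abs(refit$components)), 1e-12)
})

test_that("violations aggregate by arithmetic mean per class", {
  pep <- toy3()
  fx <- make_star(pep, n_distance = 5, n_violated = 1,
                  violation_magnitude = 0.05, n_dihedral = 2, seed = 13)
  conv <- convert_restraints(parse_star(fx$text),
                             read_topology(pep$topology))
  rep <- violations(pep$ensemble$models[[1]], conv)
  expect_equal(nrow(rep$distance), 5)
  expect_equal(sum(rep$distance$violation > 1e-3), 1)
  expect_equal(max(rep$distance$violation), 0.05, tolerance = 1e-3)
  expect_equal(unname(rep$means["distance"]),
               sum(rep$distance$violation) / 5)
  expect_equal(unname(rep$means["dihedral"]), 0)
  # energy is zero iff violation is zero for flat-bottom classes
  expect_identical(rep$distance$energy == 0, rep$distance$violation == 0)
})

test_that("a dihedral pushed outside its well reports the angular excess", {
  pep <- toy3()
  topo <- read_topology(pep$topology)
  a <- pep$ensemble$atoms
  xyz <- pep$ensemble$models[[1]]
  idx <- c(which(a$resseq == 1 & a$atom == "C"),
           which(a$resseq == 2 & a$atom == "N"),
           which(a$resseq == 2 & a$atom == "CA"),
           which(a$resseq == 2 & a$atom == "C"))
  phi <- torsion_oracle(xyz[idx, ])
  conv <- list(distances = list(),
               dihedrals = list(list(atoms = idx,
                                     phi0 = stargmx:::wrap_angle(phi + 40),
                                     dphi = 30, kfac = 1)),
               orientations = list(), config = converter_config())
  rep <- violations(xyz, conv)
  expect_equal(rep$dihedral$violation, 10, tolerance = 1e-6)
})
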