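# Construction of GROMACS-ready restraints.

toy_conversion <- function(force_field = "amber", ...) {
  pep <- toy3(force_field = force_field)
  fx <- make_star(pep, seed = 21, ...)
  list(pep = pep,
       conv = convert_restraints(
         parse_star(fx$text), read_topology(pep$topology),
         converter_config(force_field = force_field)),
       fx = fx)
}

test_that("bounds convert from angstrom to nm with the r2 margin", {
  star <- hand_star("1 1 1 ALA H 1 2 ILE H 1.8 5.0")
  pep <- toy3()
  conv <- convert_restraints(parse_star(star), read_topology(pep$topology))
  d <- conv$distances[[1]]
  expect_equal(d$r0, 0.18)
  expect_equal(d$r1, 0.50)
  expect_equal(d$r2, 0.60)
  expect_equal(d$fac, 1.0)
})

test_that("an Ala MB x Ile MD record expands to 9 pairs under one label", {
  star <- hand_star("1 1 1 ALA MB 1 2 ILE MD 1.8 5.0")
  pep <- toy3()
  conv <- convert_restraints(parse_star(star), read_topology(pep$topology))
  expect_length(conv$distances, 1)
  expect_equal(nrow(conv$distances[[1]]$pairs), 9)
  expect_equal(conv$distances[[1]]$label, 0L)
})

test_that("OR members pool their expansions under the shared label", {
  star <- hand_star(c("1 1 1 ALA MB 1 2 ILE H 1.8 5.0",
                      "1 1 3 ALA MB 1 2 ILE H 1.8 5.0"))
  pep <- toy3()
  conv <- convert_restraints(parse_star(star), read_topology(pep$topology))
  expect_length(conv$distances, 1)
  expect_equal(nrow(conv$distances[[1]]$pairs), 6)   # 3 + 3
})

test_that("labels are consecutive integers from 0 in file order", {
  out <- toy_conversion(n_distance = 7)
  expect_equal(vapply(out$conv$distances, function(d) d$label, 1L), 0:6)
})

test_that("dihedral bounds average circularly", {
  pep <- toy3()
  topo <- read_topology(pep$topology)
  rec <- function(lo, hi) list(
    restraint_id = 1L,
    atoms = list(atom_spec(resseq = 1, resname = "ALA", atom = "C"),
                 atom_spec(resseq = 2, resname = "ILE", atom = "N"),
                 atom_spec(resseq = 2, resname = "ILE", atom = "CA"),
                 atom_spec(resseq = 2, resname = "ILE", atom = "C")),
    angle_lower = lo, angle_upper = hi, angle_name = "PHI")
  d1 <- build_dihedral(rec(-100, -40), topo)
  expect_equal(d1$phi0, -70)
  expect_equal(d1$dphi, 30)
  # interval crossing the periodic boundary; oracle: unit-vector mean
  d2 <- build_dihedral(rec(170, -170), topo)
  expect_equal(d2$phi0, 180)
  expect_equal(abs(circular_midpoint_oracle(170, -170)), 180)
  expect_equal(d2$dphi, 10)
  d3 <- build_dihedral(rec(-60, -60), topo)
  expect_equal(d3$phi0, -60)
  expect_equal(d3$dphi, 0)
  expect_error(build_dihedral(rec(-180, 180), topo), "full circle")
})

test_that("phi0 of every converted dihedral agrees with the vector oracle", {
  set.seed(5)
  pep <- toy3()
  topo <- read_topology(pep$topology)
  for (i in 1:20) {
    mid <- runif(1, -180, 180)
    half <- runif(1, 0, 80)
    rec <- list(restraint_id = i,
                atoms = list(atom_spec(resseq = 1, resname = "ALA", atom = "C"),
                             atom_spec(resseq = 2, resname = "ILE", atom = "N"),
                             atom_spec(resseq = 2, resname = "ILE", atom = "CA"),
                             atom_spec(resseq = 2, resname = "ILE", atom = "C")),
                angle_lower = mid - half, angle_upper = mid + half,
                angle_name = "")
    d <- build_dihedral(rec, topo)
    expect_equal(stargmx:::wrap_angle(d$phi0 -
                   circular_midpoint_oracle(mid - half, mid + half)), 0,
                 tolerance = 1e-9)
    expect_equal(d$dphi, half)
    expect_true(d$phi0 > -180 && d$phi0 <= 180)
  }
})

test_that("orientation restraints copy the observed coupling and renumber", {
  out <- toy_conversion(n_distance = 1, n_rdc = 2)
  ors <- out$conv$orientations
  expect_length(ors, 2)
  expect_equal(vapply(ors, function(o) o$experiment, 1L), c(1L, 1L))
  expect_equal(vapply(ors, function(o) o$label, 1L), c(1L, 2L))
  parsed <- parse_star(out$fx$text)
  expect_equal(vapply(ors, function(o) o$obs, 1),
               vapply(parsed$orientations, function(o) o$observed, 1))
  expect_equal(ors[[1]]$alpha, 3)
})

test_that("unresolvable atoms skip the restraint and keep the count sheet", {
  star <- hand_star(c("1 1 1 ALA H   1 2 ILE H  1.8 5.0",
                      "2 1 1 ALA HD1 1 2 ILE H  1.8 5.0"))  # no HD1 on Ala
  pep <- toy3()
  conv <- convert_restraints(parse_star(star), read_topology(pep$topology))
  expect_equal(unname(conv$counts["parsed", "distance"]), 2)
  expect_equal(unname(conv$counts["emitted", "distance"]), 1)
  expect_equal(unname(conv$counts["skipped", "distance"]), 1)
  expect_match(conv$warnings, "HD1", all = FALSE)
  expect_true(all(conv$counts["parsed", ] ==
                    conv$counts["emitted", ] + conv$counts["skipped", ]))
})

test_that("itp writers emit the documented dialects", {
  out <- toy_conversion(n_distance = 2, n_dihedral = 1, n_rdc = 1)
  dis <- strsplit(write_itp(out$conv, "distance"), "\n")[[1]]
  expect_identical(dis[2], "[ distance_restraints ]")
  body <- dis[!startsWith(dis, ";") & !startsWith(dis, "[") &
                nzchar(dis)]
  first <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  expect_length(first, 9)                       # ai aj 1 label 1 r0 r1 r2 fac
  expect_equal(first[3], 1)
  expect_equal(first[5], 1)
  expect_equal(first[4], 0)                     # first label
  dih <- strsplit(write_itp(out$conv, "dihedral"), "\n")[[1]]
  expect_identical(dih[2], "[ dihedral_restraints ]")
  dbody <- dih[!startsWith(dih, ";") & !startsWith(dih, "[") & nzchar(dih)]
  expect_length(as.numeric(strsplit(trimws(dbody[1]), "\\s+")[[1]]), 8)
  ori <- strsplit(write_itp(out$conv, "orientation"), "\n")[[1]]
  expect_identical(ori[2], "[ orientation_restraints ]")
  obody <- ori[!startsWith(ori, ";") & !startsWith(ori, "[") & nzchar(ori)]
  expect_length(as.numeric(strsplit(trimws(obody[1]), "\\s+")[[1]]), 9)
  # empty list: section header only
  empty <- write_itp(list(), "distance")
  expect_match(empty, "\\[ distance_restraints \\]")
  expect_length(grep("^ *[0-9]", strsplit(empty, "\n")[[1]]), 0)
})

test_that("the mdp fragment carries the configured constants", {
  frag <- write_mdp_fragment(converter_config())
  expect_match(frag, "disre-fc *= 1000")
  expect_match(frag, "disre-tau *= 500")
  expect_match(frag, "orire-fc *= 10")
  zero <- write_mdp_fragment(converter_config(k_dr = 0, tau_dr = 0,
                                              k_dihr = 0, k_or = 0))
  expect_match(zero, "disre-fc *= 0")
  expect_match(zero, "orire-fc *= 0")
})

test_that("conversion is deterministic: identical inputs, identical bytes", {
  run <- function() {
    out <- toy_conversion(n_distance = 4, n_dihedral = 1, n_rdc = 1)
    paste(write_itp(out$conv, "distance"), write_itp(out$conv, "dihedral"),
          write_itp(out$conv, "orientation"))
  }
  expect_identical(run(), run())
})

test_that("emitted geometry stays in physical ranges", {
  out <- toy_conversion(n_distance = 8, n_dihedral = 2)
  for (d in out$conv$distances) {
    expect_true(d$r0 >= 0 && d$r0 <= d$r1 && d$r1 <= d$r2)
    expect_true(d$r2 > 0 && d$r2 <= 10)
  }
  for (d in out$conv$dihedrals)
    expect_true(d$phi0 > -180 && d$phi0 <= 180 && d$dphi >= 0)
})
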