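# Shared toy systems built in code at test time.

toy3 <- function(force_field = "amber", n_models = 3, seed = 11)
  make_peptide(c("ALA", "ILE", "ALA"), n_models = n_models, seed = seed,
               force_field = force_field)

# Independent torsion-angle oracle (degrees), straight from the
# cross-product definition.
torsion_oracle <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Circular-midpoint oracle via the unit-vector mean of the two endpoint
# directions (valid for arcs < 180 degrees).
circular_midpoint_oracle <- function(lo, hi) {
  a <- c(lo, hi) * pi / 180
  atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
}

# Minimal NMR-STAR distance loop writer for hand-built fixtures.
hand_star <- function(rows) {
  paste(c("data_test", "save_dist",
          "   loop_",
          "      _Gen_dist_constraint.ID",
          "      _Gen_dist_constraint.Entity_assembly_ID_1",
          "      _Gen_dist_constraint.Comp_index_ID_1",
          "      _Gen_dist_constraint.Comp_ID_1",
          "      _Gen_dist_constraint.Atom_ID_1",
          "      _Gen_dist_constraint.Entity_assembly_ID_2",
          "      _Gen_dist_constraint.Comp_index_ID_2",
          "      _Gen_dist_constraint.Comp_ID_2",
          "      _Gen_dist_constraint.Atom_ID_2",
          "      _Gen_dist_constraint.Distance_lower_bound_val",
          "      _Gen_dist_constraint.Distance_upper_bound_val",
          rows,
          "   stop_", "save_"), collapse = "\n")
}
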