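# Two-layer nomenclature translation: NMR identifiers -> real atoms ->
# force-field names.

test_that("every translation rule row is applied for both force fields", {
  tab <- load_translation_table()
  expect_gt(nrow(tab), 25)
  for (r in seq_len(nrow(tab))) {
    residues <- tab$residues[[r]]
    if (identical(residues, "*")) residues <- "ALA"
    for (res in residues) {
      out_a <- translate_atom(res, tab$identifier[r], "amber")
      out_c <- translate_atom(res, tab$identifier[r], "charmm")
      expect_identical(as.character(out_a), tab$amber[[r]],
                       info = paste(res, tab$identifier[r], "amber"))
      expect_identical(as.character(out_c), tab$charmm[[r]],
                       info = paste(res, tab$identifier[r], "charmm"))
      expect_true(attr(out_a, "translated"))
    }
  }
})

test_that("amber and charmm outputs differ exactly where the table differs", {
  tab <- load_translation_table()
  for (r in seq_len(nrow(tab))) {
    res <- if (identical(tab$residues[[r]], "*")) "GLY"
           else tab$residues[[r]][1]
    a <- translate_atom(res, tab$identifier[r], "amber")
    c <- translate_atom(res, tab$identifier[r], "charmm")
    if (identical(tab$amber[[r]], tab$charmm[[r]])) {
      expect_identical(as.character(a), as.character(c))
    } else {
      expect_false(identical(as.character(a), as.character(c)))
    }
  }
  # the two known divergences
  expect_identical(as.character(translate_atom("ALA", "H", "charmm")), "HN")
  expect_identical(as.character(translate_atom("ALA", "H", "amber")), "H")
  expect_identical(as.character(translate_atom("SER", "HG", "charmm")), "HG1")
  expect_identical(as.character(translate_atom("SER", "HG", "amber")), "HG")
})

test_that("pseudo-atom expansion covers methyls, shifts and pass-through", {
  expect_identical(as.character(translate_atom("ALA", "MB", "amber")),
                   c("HB1", "HB2", "HB3"))
  expect_identical(as.character(translate_atom("GLY", "HA2", "amber")),
                   "HA1")
  expect_identical(as.character(translate_atom("LYS", "HB2", "amber")),
                   "HB1")
  expect_identical(as.character(translate_atom("DT", "M7", "charmm")),
                   c("H71", "H72", "H73"))
  expect_identical(as.character(translate_atom("G", "H5''", "amber")),
                   "H5'2")
  # identity pass-through, flagged untranslated
  out <- translate_atom("ALA", "CA", "amber")
  expect_identical(as.character(out), "CA")
  expect_false(attr(out, "translated"))
  # unknown residue: identifier passes through rather than failing
  expect_identical(as.character(translate_atom("XYZ", "MB", "amber")), "MB")
})

test_that("matching is case-insensitive and prime-normalized", {
  expect_identical(as.character(translate_atom("ala", "mb", "amber")),
                   c("HB1", "HB2", "HB3"))
  expect_identical(as.character(translate_atom("G", "H5″", "amber")),
                   "H5'2")
  expect_identical(as.character(translate_atom("G", "H2′", "amber")),
                   "H2'1")
})

test_that("expand_pair is the Cartesian product in deterministic order", {
  a <- atom_spec(resseq = 1, resname = "ALA", atom = "MB")
  b <- atom_spec(resseq = 2, resname = "ILE", atom = "MD")
  pairs <- expand_pair(a, b, "amber")
  expect_equal(nrow(pairs), 9)
  expect_identical(pairs$atom_1,
                   rep(c("HB1", "HB2", "HB3"), each = 3))
  expect_identical(pairs$atom_2, rep(c("HD1", "HD2", "HD3"), 3))
  expect_identical(unique(pairs$origin_1), "MB")
  # singleton x singleton
  g <- atom_spec(resseq = 1, resname = "GLY", atom = "HA2")
  h <- atom_spec(resseq = 2, resname = "ALA", atom = "H")
  expect_equal(nrow(expand_pair(g, h, "amber")), 1)
  # two leucine methyls: 3 x 3, never self-paired
  l1 <- atom_spec(resseq = 5, resname = "LEU", atom = "MD1")
  l2 <- atom_spec(resseq = 5, resname = "LEU", atom = "MD2")
  p <- expand_pair(l1, l2, "amber")
  expect_equal(nrow(p), 9)
  expect_true(all(p$atom_1 != p$atom_2))
})

test_that("expand_pair length is always the product of the translations", {
  tab <- load_translation_table()
  set.seed(42)
  for (i in sample(nrow(tab), 10)) {
    for (j in sample(nrow(tab), 5)) {
      res_i <- if (identical(tab$residues[[i]], "*")) "ALA"
               else tab$residues[[i]][1]
      res_j <- if (identical(tab$residues[[j]], "*")) "ALA"
               else tab$residues[[j]][1]
      a <- atom_spec(resseq = 1, resname = res_i, atom = tab$identifier[i])
      b <- atom_spec(resseq = 2, resname = res_j, atom = tab$identifier[j])
      expect_equal(nrow(expand_pair(a, b, "charmm")),
                   length(translate_atom(res_i, tab$identifier[i], "charmm")) *
                     length(translate_atom(res_j, tab$identifier[j], "charmm")))
    }
  }
})

test_that("dihedral translation requires single-atom identifiers", {
  rec <- list(restraint_id = 7, atoms = list(
    atom_spec(resseq = 1, resname = "ALA", atom = "C"),
    atom_spec(resseq = 2, resname = "ALA", atom = "N"),
    atom_spec(resseq = 2, resname = "ALA", atom = "CA"),
    atom_spec(resseq = 2, resname = "ALA", atom = "C")))
  expect_identical(translate_dihedral(rec, "amber"),
                   c("C", "N", "CA", "C"))
  # backbone H renames per force field
  rec$atoms[[2]] <- atom_spec(resseq = 2, resname = "ALA", atom = "H")
  expect_identical(translate_dihedral(rec, "charmm")[2], "HN")
  # degenerate group in a torsion is a hard error naming the restraint
  rec$atoms[[2]] <- atom_spec(resseq = 2, resname = "ALA", atom = "MB")
  expect_error(translate_dihedral(rec, "amber"), "7")
})
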