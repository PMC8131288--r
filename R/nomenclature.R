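#' @title Pseudo-atom and force-field nomenclature translation
#'
#' @description NMR depositions address degenerate proton groups with
#' pseudo-atom identifiers (MB for an alanine methyl, QD for the two
#' delta protons of an aromatic ring) and use deposition atom names that
#' differ from force-field atom names (backbone amide H vs Charmm HN,
#' HB2/HB3 vs HB1/HB2).  Conversion therefore runs in two layers: first
#' from the NMR identifier to the set of real atoms it denotes, then to
#' the atom names of the chosen force field.  Both layers are driven by a
#' plain-text rule table shipped with the package
#' (`system.file("extdata", "atom_translations.tsv", package = "stargmx")`)
#' which users can extend for other force fields or non-standard residues.
#'
#' @name nomenclature
NULL

.stargmx_env <- new.env(parent = emptyenv())

# Normalize residue / atom identifiers: upper case, typographic primes and
# double-primes mapped to ASCII.
normalize_id <- function(x) {
  x <- toupper(x)
  x <- gsub("″|”", "''", x)
  gsub("′|’|`", "'", x)
}

#' Load the atom translation rule table
#'
#' @param path Path to a tab-separated rule file with columns
#'   `residues` (comma-separated codes or `*`), `identifier`,
#'   `amber`, `charmm` (comma-separated target atom names).  Defaults to
#'   the table shipped with the package.
#' @return A data frame with list-columns `residues`, `amber`, `charmm`
#'   and a character column `identifier`.
#' @export
load_translation_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.stargmx_env$translation_table))
      return(.stargmx_env$translation_table)
    path <- system.file("extdata", "atom_translations.tsv",
                        package = "stargmx", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("residues", "identifier", "amber", "charmm") %in%
                  names(raw)))
  split_targets <- function(s) strsplit(normalize_id(s), ",", fixed = TRUE)
  tab <- data.frame(identifier = normalize_id(raw$identifier),
                    stringsAsFactors = FALSE)
  tab$residues <- split_targets(raw$residues)
  tab$amber <- split_targets(raw$amber)
  tab$charmm <- split_targets(raw$charmm)
  bad <- lengths(tab$amber) != lengths(tab$charmm)
  if (any(bad))
    stop("translation rule(s) with unequal Amber/Charmm target lengths: ",
         paste(tab$identifier[bad], collapse = ", "))
  # Deduplicate identical (residues, identifier) rows; the reference table
  # repeats some shift rules verbatim.
  key <- paste(vapply(tab$residues, paste, "", collapse = ","),
               tab$identifier)
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  if (cache) .stargmx_env$translation_table <- tab
  tab
}

#' Translate one NMR atom identifier to force-field atom names
#'
#' Expands a (possibly pseudo-atom) identifier to the real atom names it
#' denotes in the chosen force field, in subscript order.  Identifiers with
#' no applicable rule pass through unchanged as a singleton, so unknown
#' residues or already-concrete names are handled gracefully; matching is
#' case-insensitive and typographic primes are normalized.
#'
#' @param residue_name Residue code (3-letter amino acid, or nucleotide
#'   code G/A/U/C/DG/DA/DT/DC).
#' @param identifier NMR atom identifier (e.g. `"MB"`, `"HB2"`, `"CA"`).
#' @param force_field `"amber"` or `"charmm"`.
#' @param table Rule table from [load_translation_table()].
#' @return Character vector of one or more real atom names.  The attribute
#'   `"translated"` is `TRUE` when a rule applied.
#' @examples
#' translate_atom("ALA", "MB", "amber")    # HB1 HB2 HB3
#' translate_atom("GLY", "HA2", "amber")   # HA1
#' translate_atom("SER", "HG", "charmm")   # HG1
#' @export
translate_atom <- function(residue_name, identifier,
                           force_field = c("amber", "charmm"),
                           table = load_translation_table()) {
  force_field <- match.arg(force_field)
  res <- normalize_id(residue_name)
  id <- normalize_id(identifier)
  hit <- which(table$identifier == id &
                 vapply(table$residues,
                        function(r) identical(r, "*") || res %in% r,
                        logical(1)))
  if (length(hit) == 0)
    return(structure(id, translated = FALSE))
  structure(table[[force_field]][[hit[1]]], translated = TRUE)
}

#' Expand an atom pair through pseudo-atom translation
#'
#' The Cartesian product of the two translated atom lists: an Ala MB
#' (3 protons) paired with an Ile MD (3 protons) expands to 9 concrete
#' atom pairs, all of which belong to one restraint.  Order is
#' deterministic: outer loop over the first atom's targets, inner loop
#' over the second's, each in subscript order.
#'
#' @param a,b Atom specifications: lists with elements `chain`, `resseq`,
#'   `resname`, `atom` (see [atom_spec()]).
#' @param force_field `"amber"` or `"charmm"`.
#' @param table Rule table.
#' @return A data frame with one row per expanded pair and columns
#'   `chain_1`, `resseq_1`, `resname_1`, `atom_1`, `origin_1` and the
#'   `_2` equivalents; `origin_*` carries the NMR identifier each real
#'   atom came from.
#' @examples
#' a <- atom_spec(resseq = 1, resname = "ALA", atom = "MB")
#' b <- atom_spec(resseq = 2, resname = "ILE", atom = "MD")
#' nrow(expand_pair(a, b))   # 9
#' @export
expand_pair <- function(a, b, force_field = c("amber", "charmm"),
                        table = load_translation_table()) {
  force_field <- match.arg(force_field)
  ta <- translate_atom(a$resname, a$atom, force_field, table)
  tb <- translate_atom(b$resname, b$atom, force_field, table)
  grid <- expand.grid(atom_2 = tb, atom_1 = ta,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(chain_1 = a$chain, resseq_1 = a$resseq, resname_1 = a$resname,
             atom_1 = as.character(grid$atom_1), origin_1 = a$atom,
             chain_2 = b$chain, resseq_2 = b$resseq, resname_2 = b$resname,
             atom_2 = as.character(grid$atom_2), origin_2 = b$atom,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Translate the four atoms of a dihedral restraint
#'
#' Dihedral restraints name four individual atoms; a degenerate-group
#' identifier is illegal there, so an identifier expanding to more than
#' one real atom is a hard error naming the restraint.
#'
#' @param record A raw dihedral record (see [parse_star()]).
#' @param force_field `"amber"` or `"charmm"`.
#' @param table Rule table.
#' @return Character vector of four concrete atom names, in input order.
#' @export
translate_dihedral <- function(record, force_field = c("amber", "charmm"),
                               table = load_translation_table()) {
  force_field <- match.arg(force_field)
  vapply(record$atoms, function(a) {
    t <- translate_atom(a$resname, a$atom, force_field, table)
    if (length(t) != 1)
      stop(sprintf(
        "dihedral restraint %s: identifier %s on %s %d denotes %d atoms",
        record$restraint_id, a$atom, a$resname, a$resseq, length(t)))
    t
  }, character(1))
}
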