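#' Atom specification
#'
#' Address of one atom (or pseudo-atom) in an NMR deposition: chain
#' (entity assembly) label, author residue sequence number, residue code,
#' and the NMR atom identifier.
#'
#' @param chain Chain label; entity assembly ids 1, 2, ... map to
#'   "A", "B", ....
#' @param resseq Author residue sequence number (>= 1).
#' @param resname Residue code (3-letter amino acid or G/A/U/C/DG/DA/DT/DC).
#' @param atom NMR atom identifier; may be a pseudo-atom such as MB or QD.
#' @return A list of class `"atom_spec"`.
#' @export
atom_spec <- function(chain = "A", resseq, resname, atom) {
  resseq <- as.integer(resseq)
  stopifnot(length(resseq) == 1, !is.na(resseq), resseq >= 1,
            nzchar(atom))
  structure(list(chain = as.character(chain), resseq = resseq,
                 resname = normalize_id(resname),
                 atom = normalize_id(atom)),
            class = "atom_spec")
}

# ---------------------------------------------------------------------------
# Low-level STAR machinery: tokenizer + loop scanner.  Only the features
# needed for restraint loops are implemented: data_/save_ frames, loop_
# blocks with tag lists and whitespace-separated (possibly quoted) values
# that may wrap across lines, ';'-delimited multiline values, '#' comments.
# ---------------------------------------------------------------------------

star_tokenize <- function(line) {
  m <- gregexpr("\"[^\"]*\"|'[^']*'(?=\\s|$)|\\S+", line, perl = TRUE)
  toks <- regmatches(line, m)[[1]]
  vapply(toks, function(t) {
    if (nchar(t) >= 2 &&
        ((startsWith(t, "\"") && endsWith(t, "\"")) ||
         (startsWith(t, "'") && endsWith(t, "'"))))
      substr(t, 2, nchar(t) - 1)
    else t
  }, character(1), USE.NAMES = FALSE)
}

# Scan STAR text into a list of loops, each a list(tags, values, frame).
star_scan_loops <- function(lines) {
  loops <- list()
  frame <- NA_character_
  i <- 1L
  n <- length(lines)
  strip <- function(s) sub("\\s*(#.*)?$", "", s)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "save_")) {
      frame <- if (nchar(ln) > 5) substring(ln, 6) else NA_character_
      i <- i + 1L
      next
    }
    if (ln == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(trimws(lines[[i]]), "_")) {
        tags <- c(tags, star_tokenize(strip(trimws(lines[[i]])))[1])
        i <- i + 1L
      }
      values <- character()
      while (i <= n) {
        ln2 <- trimws(lines[[i]])
        if (ln2 %in% c("stop_", "loop_") || startsWith(ln2, "save_") ||
            startsWith(ln2, "_") || startsWith(ln2, "data_"))
          break
        if (startsWith(ln2, ";")) {               # multiline value block
          i <- i + 1L
          block <- character()
          while (i <= n && !startsWith(trimws(lines[[i]]), ";")) {
            block <- c(block, lines[[i]])
            i <- i + 1L
          }
          values <- c(values, paste(block, collapse = "\n"))
          i <- i + 1L
          next
        }
        if (!startsWith(ln2, "#") && nzchar(ln2))
          values <- c(values, star_tokenize(strip(ln2)))
        i <- i + 1L
      }
      if (length(tags) > 0 && length(values) %% length(tags) != 0)
        stop(sprintf(
          "malformed STAR loop in save frame '%s': %d values for %d tags",
          ifelse(is.na(frame), "<none>", frame),
          length(values), length(tags)))
      if (length(tags) > 0)
        loops[[length(loops) + 1L]] <-
          list(tags = tags, frame = frame,
               rows = matrix(values, ncol = length(tags), byrow = TRUE,
                             dimnames = list(NULL, tags)))
      next
    }
    i <- i + 1L
  }
  loops
}

# Find the loop column whose tag ends in ".<name>" (case-insensitive);
# returns NA if absent.
star_col <- function(rows, name) {
  tags <- tolower(colnames(rows))
  hit <- which(endsWith(tags, paste0(".", tolower(name))))
  if (length(hit) == 0) return(rep(NA_character_, nrow(rows)))
  v <- rows[, hit[1]]
  v[v %in% c(".", "?")] <- NA_character_
  v
}

star_num <- function(x) suppressWarnings(as.numeric(x))

chain_from_entity <- function(entity) {
  idx <- suppressWarnings(as.integer(entity))
  out <- ifelse(!is.na(idx) & idx >= 1 & idx <= 26, LETTERS[pmax(idx, 1)],
                as.character(entity))
  out[is.na(entity)] <- "A"
  out
}

entity_from_chain <- function(chain) {
  idx <- match(chain, LETTERS)
  ifelse(is.na(idx), chain, as.character(idx))
}

star_atom_specs <- function(rows, k) {
  ent <- star_col(rows, sprintf("Entity_assembly_ID_%d", k))
  seqno <- star_col(rows, sprintf("Auth_seq_ID_%d", k))
  alt <- star_col(rows, sprintf("Comp_index_ID_%d", k))
  if (all(is.na(seqno))) seqno <- alt else seqno[is.na(seqno)] <- alt[is.na(seqno)]
  if (all(is.na(seqno))) seqno <- star_col(rows, sprintf("Seq_ID_%d", k))
  comp <- star_col(rows, sprintf("Comp_ID_%d", k))
  atom <- star_col(rows, sprintf("Atom_ID_%d", k))
  list(chain = chain_from_entity(ent), resseq = star_num(seqno),
       resname = comp, atom = atom)
}

# ---------------------------------------------------------------------------
# Loop classification and record extraction
# ---------------------------------------------------------------------------

classify_loop <- function(tags) {
  t <- tolower(tags)
  if (any(grepl("gen_dist_constraint\\.|dist_constraint\\.|distance_constraint\\.",
                t)))
    return("distance")
  if (any(grepl("torsion_angle_constraint\\.|dihedral_constraint\\.", t)))
    return("dihedral")
  if (any(grepl("rdc_constraint\\.|rdc\\.", t)))
    return("orientation")
  # dialect fallback: decide from the bound columns present
  has <- function(p) any(grepl(p, t))
  if (has("atom_id_4") && has("angle_lower_bound")) return("dihedral")
  if (has("atom_id_2") && has("rdc_val")) return("orientation")
  if (has("atom_id_2") && (has("lower_bound") || has("upper_bound") ||
                             has("distance_val")))
    return("distance")
  "other"
}

extract_distance_loop <- function(loop, warnings) {
  rows <- loop$rows
  a1 <- star_atom_specs(rows, 1)
  a2 <- star_atom_specs(rows, 2)
  id <- star_num(star_col(rows, "ID"))
  if (all(is.na(id))) id <- seq_len(nrow(rows))
  lower <- star_num(star_col(rows, "Distance_lower_bound_val"))
  upper <- star_num(star_col(rows, "Distance_upper_bound_val"))
  target <- star_num(star_col(rows, "Distance_val"))
  err <- star_num(star_col(rows, "Distance_val_err"))
  # (target, +/- tolerance) dialect -> lower/upper at parse time
  use_tgt <- is.na(upper) & !is.na(target)
  upper[use_tgt] <- target[use_tgt] +
    ifelse(is.na(err[use_tgt]), 0, err[use_tgt])
  lower[use_tgt & is.na(lower)] <- pmax(
    0, target[use_tgt & is.na(lower)] -
      ifelse(is.na(err[use_tgt & is.na(lower)]), 0,
             err[use_tgt & is.na(lower)]))
  lower[is.na(lower)] <- 0            # upper-bound-only NOE
  records <- list()
  for (r in seq_len(nrow(rows))) {
    if (is.na(upper[r]) || is.na(id[r]) || is.na(a1$resseq[r]) ||
        is.na(a2$resseq[r]) || is.na(a1$atom[r]) || is.na(a2$atom[r])) {
      warnings <- c(warnings, sprintf(
        "skipping distance restraint row %d (id %s): unparsable fields",
        r, format(id[r])))
      next
    }
    key <- as.character(id[r])
    member <- list(atom_spec(a1$chain[r], a1$resseq[r], a1$resname[r],
                             a1$atom[r]),
                   atom_spec(a2$chain[r], a2$resseq[r], a2$resname[r],
                             a2$atom[r]))
    if (is.null(records[[key]])) {
      records[[key]] <- list(restraint_id = as.integer(id[r]),
                             members = list(member),
                             lower_bound = lower[r], upper_bound = upper[r],
                             target = target[r])
    } else {
      records[[key]]$members <- c(records[[key]]$members, list(member))
    }
  }
  list(records = unname(records), warnings = warnings)
}

extract_dihedral_loop <- function(loop, warnings) {
  rows <- loop$rows
  id <- star_num(star_col(rows, "ID"))
  if (all(is.na(id))) id <- seq_len(nrow(rows))
  name <- star_col(rows, "Torsion_angle_name")
  lower <- star_num(star_col(rows, "Angle_lower_bound_val"))
  upper <- star_num(star_col(rows, "Angle_upper_bound_val"))
  specs <- lapply(1:4, function(k) star_atom_specs(rows, k))
  records <- list()
  for (r in seq_len(nrow(rows))) {
    ok <- !is.na(lower[r]) && !is.na(upper[r]) &&
      all(vapply(specs, function(s) !is.na(s$resseq[r]) && !is.na(s$atom[r]),
                 logical(1)))
    if (!ok) {
      warnings <- c(warnings, sprintf(
        "skipping dihedral restraint row %d (id %s): unparsable fields",
        r, format(id[r])))
      next
    }
    atoms <- lapply(specs, function(s)
      atom_spec(s$chain[r], s$resseq[r], s$resname[r], s$atom[r]))
    records[[length(records) + 1L]] <-
      list(restraint_id = as.integer(id[r]), atoms = atoms,
           angle_lower = lower[r], angle_upper = upper[r],
           angle_name = ifelse(is.na(name[r]), "", name[r]))
  }
  list(records = records, warnings = warnings)
}

extract_orientation_loop <- function(loop, warnings, experiment_id) {
  rows <- loop$rows
  id <- star_num(star_col(rows, "ID"))
  if (all(is.na(id))) id <- seq_len(nrow(rows))
  obs <- star_num(star_col(rows, "RDC_val"))
  err <- star_num(star_col(rows, "RDC_val_err"))
  a1 <- star_atom_specs(rows, 1)
  a2 <- star_atom_specs(rows, 2)
  records <- list()
  for (r in seq_len(nrow(rows))) {
    if (is.na(obs[r]) || is.na(a1$resseq[r]) || is.na(a2$resseq[r]) ||
        is.na(a1$atom[r]) || is.na(a2$atom[r])) {
      warnings <- c(warnings, sprintf(
        "skipping orientation restraint row %d (id %s): unparsable fields",
        r, format(id[r])))
      next
    }
    records[[length(records) + 1L]] <-
      list(restraint_id = as.integer(id[r]),
           atoms = list(atom_spec(a1$chain[r], a1$resseq[r], a1$resname[r],
                                  a1$atom[r]),
                        atom_spec(a2$chain[r], a2$resseq[r], a2$resname[r],
                                  a2$atom[r])),
           observed = obs[r], error = err[r],
           experiment_id = experiment_id)
  }
  list(records = records, warnings = warnings)
}

#' Parse restraint loops from NMR-STAR text
#'
#' Reads the distance (NOE), torsion-angle and residual-dipolar-coupling
#' constraint loops of an NMR-STAR v3 file into raw typed records.  Rows of
#' a distance loop that share one constraint ID are logical-OR alternatives
#' and become members of a single record.  Both the deposited
#' `Gen_dist_constraint`-style loops and simpler two-atom loops are
#' accepted; the dialect is detected from the loop tags.  Bounds stated as
#' (target value, error) are converted to lower/upper bounds here so that
#' downstream code sees one representation.  Units are as deposited
#' (angstrom, degrees, Hz); conversion to nm happens at restraint build
#' time, never here.
#'
#' @param x NMR-STAR content: a file path, or a character vector of lines
#'   (or one string containing newlines).
#' @param source_label Label recorded on the returned object.
#' @return An object of class `"restraint_sets"`: a list with elements
#'   `distances`, `dihedrals`, `orientations` (lists of raw records),
#'   `source_label`, `warnings` (character), and `n_rows` (rows seen per
#'   class, for count bookkeeping).
#' @examples
#' star <- make_star(make_peptide(c("ALA", "ILE")), n_distance = 2, seed = 1)
#' sets <- parse_star(star$text)
#' length(sets$distances)
#' @export
parse_star <- function(x, source_label = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(source_label)) source_label <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(source_label)) source_label <- "nmr-star"
  loops <- star_scan_loops(lines)
  distances <- list(); dihedrals <- list(); orientations <- list()
  warnings <- character()
  n_rows <- c(distance = 0L, dihedral = 0L, orientation = 0L)
  n_rdc_loops <- 0L
  for (loop in loops) {
    kind <- classify_loop(loop$tags)
    if (kind == "distance") {
      n_rows["distance"] <- n_rows["distance"] + nrow(loop$rows)
      out <- extract_distance_loop(loop, warnings)
      distances <- c(distances, out$records)
      warnings <- out$warnings
    } else if (kind == "dihedral") {
      n_rows["dihedral"] <- n_rows["dihedral"] + nrow(loop$rows)
      out <- extract_dihedral_loop(loop, warnings)
      dihedrals <- c(dihedrals, out$records)
      warnings <- out$warnings
    } else if (kind == "orientation") {
      n_rows["orientation"] <- n_rows["orientation"] + nrow(loop$rows)
      n_rdc_loops <- n_rdc_loops + 1L
      out <- extract_orientation_loop(loop, warnings, n_rdc_loops)
      orientations <- c(orientations, out$records)
      warnings <- out$warnings
    }
  }
  structure(list(distances = distances, dihedrals = dihedrals,
                 orientations = orientations,
                 source_label = source_label,
                 warnings = warnings, n_rows = n_rows),
            class = "restraint_sets")
}

#' @export
print.restraint_sets <- function(x, ...) {
  cat(sprintf("Restraint sets from '%s'\n", x$source_label))
  cat(sprintf("  distance restraints    : %d (%d OR members)\n",
              length(x$distances),
              sum(vapply(x$distances, function(d) length(d$members), 1L))))
  cat(sprintf("  dihedral restraints    : %d\n", length(x$dihedrals)))
  cat(sprintf("  orientation restraints : %d\n", length(x$orientations)))
  if (length(x$warnings))
    cat(sprintf("  warnings               : %d\n", length(x$warnings)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Writer (debug format / fixture emission): serializes restraint sets back
# to NMR-STAR so that parse_star(write_star(x)) round-trips.
# ---------------------------------------------------------------------------

fmt_star_num <- function(x) {
  ifelse(is.na(x), ".", vapply(x, function(v) format(v, digits = 12),
                               character(1)))
}

#' Serialize restraint sets to NMR-STAR text
#'
#' Writes the package's raw restraint records back out as NMR-STAR v3
#' loops (`Gen_dist_constraint`, `Torsion_angle_constraint`,
#' `RDC_constraint`).  Used both as the debug round-trip format and by the
#' fixture generator.
#'
#' @param sets A `"restraint_sets"` object.
#' @return A single string of NMR-STAR text.
#' @export
write_star <- function(sets) {
  out <- c("data_restraints", "")
  pad <- function(x, w) formatC(x, width = w)
  if (length(sets$distances) > 0) {
    out <- c(out, "save_distance_constraints",
             "   _Gen_dist_constraint_list.Sf_category general_distance_constraints",
             "   loop_")
    tags <- c("ID", "Entity_assembly_ID_1", "Comp_index_ID_1", "Comp_ID_1",
              "Atom_ID_1", "Entity_assembly_ID_2", "Comp_index_ID_2",
              "Comp_ID_2", "Atom_ID_2", "Distance_lower_bound_val",
              "Distance_upper_bound_val", "Distance_val")
    out <- c(out, sprintf("      _Gen_dist_constraint.%s", tags))
    for (rec in sets$distances) {
      for (m in rec$members) {
        out <- c(out, paste("     ",
          pad(rec$restraint_id, 4),
          entity_from_chain(m[[1]]$chain), pad(m[[1]]$resseq, 4),
          pad(m[[1]]$resname, 4), pad(m[[1]]$atom, 6),
          entity_from_chain(m[[2]]$chain), pad(m[[2]]$resseq, 4),
          pad(m[[2]]$resname, 4), pad(m[[2]]$atom, 6),
          fmt_star_num(rec$lower_bound), fmt_star_num(rec$upper_bound),
          fmt_star_num(rec$target)))
      }
    }
    out <- c(out, "   stop_", "save_", "")
  }
  if (length(sets$dihedrals) > 0) {
    out <- c(out, "save_torsion_angle_constraints",
             "   _Torsion_angle_constraint_list.Sf_category torsion_angle_constraints",
             "   loop_")
    tags <- c("ID", "Torsion_angle_name",
              unlist(lapply(1:4, function(k)
                sprintf(c("Entity_assembly_ID_%d", "Comp_index_ID_%d",
                          "Comp_ID_%d", "Atom_ID_%d"), k))),
              "Angle_lower_bound_val", "Angle_upper_bound_val")
    out <- c(out, sprintf("      _Torsion_angle_constraint.%s", tags))
    for (rec in sets$dihedrals) {
      fields <- unlist(lapply(rec$atoms, function(a)
        c(entity_from_chain(a$chain), pad(a$resseq, 4), pad(a$resname, 4),
          pad(a$atom, 5))))
      out <- c(out, paste("     ", pad(rec$restraint_id, 4),
                          ifelse(nzchar(rec$angle_name), rec$angle_name, "."),
                          paste(fields, collapse = " "),
                          fmt_star_num(rec$angle_lower),
                          fmt_star_num(rec$angle_upper)))
    }
    out <- c(out, "   stop_", "save_", "")
  }
  if (length(sets$orientations) > 0) {
    exps <- vapply(sets$orientations, function(r) r$experiment_id, 1)
    for (e in sort(unique(exps))) {
      out <- c(out, sprintf("save_RDC_constraints_%d", e),
               "   _RDC_constraint_list.Sf_category RDC_constraints",
               "   loop_")
      tags <- c("ID", "Entity_assembly_ID_1", "Comp_index_ID_1", "Comp_ID_1",
                "Atom_ID_1", "Entity_assembly_ID_2", "Comp_index_ID_2",
                "Comp_ID_2", "Atom_ID_2", "RDC_val", "RDC_val_err")
      out <- c(out, sprintf("      _RDC_constraint.%s", tags))
      for (rec in sets$orientations[exps == e]) {
        m <- rec$atoms
        out <- c(out, paste("     ",
          pad(rec$restraint_id, 4),
          entity_from_chain(m[[1]]$chain), pad(m[[1]]$resseq, 4),
          pad(m[[1]]$resname, 4), pad(m[[1]]$atom, 6),
          entity_from_chain(m[[2]]$chain), pad(m[[2]]$resseq, 4),
          pad(m[[2]]$resname, 4), pad(m[[2]]$atom, 6),
          fmt_star_num(rec$observed), fmt_star_num(rec$error)))
      }
      out <- c(out, "   stop_", "save_", "")
    }
  }
  paste(out, collapse = "\n")
}

#' Download a deposited entry's restraint and coordinate files
#'
#' Retrieves the NMR restraint file (`<id>_mr.str`, NMR-STAR v3) and the
#' multi-model PDB coordinate file for a deposited accession, caching both
#' on disk.  Requires network access.
#'
#' @param pdb_id Four-character accession code.
#' @param cache_dir Directory for cached downloads.
#' @param base_url Download server.
#' @return A list with elements `star` and `pdb`, each a character vector
#'   of file lines, plus the cached `star_path` / `pdb_path`.
#' @export
fetch_entry <- function(pdb_id,
                        cache_dir = file.path(tempdir(), "stargmx_cache"),
                        base_url = "https://files.rcsb.org/download") {
  pdb_id <- tolower(pdb_id)
  if (!grepl("^[0-9][a-z0-9]{3}$", pdb_id))
    stop("malformed accession code: ", pdb_id)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  get1 <- function(fname) {
    dest <- file.path(cache_dir, fname)
    if (!file.exists(dest)) {
      tmp <- paste0(dest, ".part")
      status <- tryCatch(
        utils::download.file(sprintf("%s/%s", base_url, fname), tmp,
                             quiet = TRUE, mode = "wb"),
        error = function(e) -1L, warning = function(w) -1L)
      if (!identical(status, 0L) || !file.exists(tmp)) {
        unlink(tmp)
        stop(sprintf("retrieval of %s failed (network or unknown entry)",
                     fname))
      }
      file.rename(tmp, dest)
    }
    dest
  }
  star_path <- get1(sprintf("%s_mr.str", pdb_id))
  pdb_path <- get1(sprintf("%s.pdb", pdb_id))
  list(star = readLines(star_path, warn = FALSE),
       pdb = readLines(pdb_path, warn = FALSE),
       star_path = star_path, pdb_path = pdb_path)
}
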