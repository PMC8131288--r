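#' Read the atom index of a GROMACS topology
#'
#' Parses the `[ atoms ]` sections of a GROMACS topology (`.top` / `.itp`)
#' into a global, 1-based atom index keyed by (chain, residue number, atom
#' name).  `#include` directives are resolved for files next to the
#' topology (or in `dir`); unresolvable includes are noted and skipped.
#' `#ifdef` blocks follow the default (undefined) path: the `#ifdef` branch
#' is dropped and the `#else` branch kept.  If a `[ molecules ]` section is
#' present, molecule types are replicated in its order and counts; each
#' replica is one chain, labeled "A", "B", ... positionally.  Without a
#' `[ molecules ]` section every declared molecule type appears once, in
#' declaration order.
#'
#' @param x Path to a topology file, or topology text (character vector of
#'   lines or one string containing newlines).
#' @param dir Directory for `#include` resolution; defaults to the file's
#'   directory, or the working directory for in-memory text.
#' @return An object of class `"topology_index"`: a list with `atoms`
#'   (data frame: `index`, `chain`, `resseq`, `resname`, `atom`),
#'   `chains` (chain labels in order) and `notes` (character).
#' @examples
#' pep <- make_peptide(c("ALA", "GLY"))
#' top <- read_topology(pep$topology)
#' nrow(top$atoms)
#' @export
read_topology <- function(x, dir = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(dir)) dir <- dirname(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    if (is.null(dir)) dir <- "."
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  notes <- character()

  # preprocessor: resolve #include, take the default path of #ifdef/#else
  preprocess <- function(lines, dir, depth = 0) {
    if (depth > 10) stop("#include nesting too deep")
    out <- character()
    skip_stack <- logical(0)
    for (ln in lines) {
      t <- trimws(ln)
      if (startsWith(t, "#ifdef")) {
        skip_stack <- c(skip_stack, TRUE); next
      }
      if (startsWith(t, "#ifndef")) {
        skip_stack <- c(skip_stack, FALSE); next
      }
      if (startsWith(t, "#else") && length(skip_stack)) {
        skip_stack[length(skip_stack)] <- !skip_stack[length(skip_stack)]
        next
      }
      if (startsWith(t, "#endif") && length(skip_stack)) {
        skip_stack <- skip_stack[-length(skip_stack)]; next
      }
      if (any(skip_stack)) next
      if (startsWith(t, "#include")) {
        fname <- gsub("^#include\\s+[\"<]?|[\">]\\s*$", "", t)
        path <- file.path(dir, fname)
        if (file.exists(path)) {
          out <- c(out, preprocess(readLines(path, warn = FALSE), dir,
                                   depth + 1))
        } else {
          notes <<- c(notes, sprintf("unresolved #include '%s' skipped",
                                     fname))
        }
        next
      }
      if (startsWith(t, "#")) next
      out <- c(out, ln)
    }
    out
  }
  lines <- preprocess(lines, dir)
  lines <- sub(";.*$", "", lines)

  section <- ""
  moltypes <- list()          # name -> data.frame(resseq, resname, atom)
  order_seen <- character()
  current <- NULL
  mols <- data.frame(name = character(), count = integer(),
                     stringsAsFactors = FALSE)
  flush_mol <- function() {
    if (!is.null(current) && nrow(current$atoms) > 0) {
      moltypes[[current$name]] <<- current$atoms
      order_seen <<- c(order_seen, current$name)
    }
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    sec <- regmatches(t, regexec("^\\[\\s*(\\S+)\\s*\\]$", t))[[1]]
    if (length(sec) == 2) { section <- tolower(sec[2]); next }
    f <- strsplit(t, "\\s+")[[1]]
    if (section == "moleculetype") {
      flush_mol()
      current <- list(name = f[1],
                      atoms = data.frame(resseq = integer(),
                                         resname = character(),
                                         atom = character(),
                                         stringsAsFactors = FALSE))
    } else if (section == "atoms") {
      if (is.null(current))          # bare [ atoms ] without moleculetype
        current <- list(name = "MOL",
                        atoms = data.frame(resseq = integer(),
                                           resname = character(),
                                           atom = character(),
                                           stringsAsFactors = FALSE))
      if (length(f) >= 5 && !is.na(suppressWarnings(as.integer(f[1]))))
        current$atoms <- rbind(current$atoms, data.frame(
          resseq = as.integer(f[3]), resname = toupper(f[4]),
          atom = normalize_id(f[5]), stringsAsFactors = FALSE))
    } else if (section == "molecules") {
      if (length(f) >= 2)
        mols <- rbind(mols, data.frame(name = f[1],
                                       count = as.integer(f[2]),
                                       stringsAsFactors = FALSE))
    }
  }
  flush_mol()
  if (length(moltypes) == 0)
    stop("no [ atoms ] section found in topology")

  # assemble chains
  chain_specs <- character()
  if (nrow(mols) > 0) {
    for (r in seq_len(nrow(mols))) {
      if (is.null(moltypes[[mols$name[r]]])) {
        notes <- c(notes, sprintf(
          "molecule '%s' in [ molecules ] has no [ atoms ] block; skipped",
          mols$name[r]))
        next
      }
      chain_specs <- c(chain_specs, rep(mols$name[r], mols$count[r]))
    }
  }
  if (length(chain_specs) == 0) chain_specs <- order_seen
  chain_label <- function(i) {
    if (i <= 26) LETTERS[i] else paste0("Z", i)
  }
  atoms <- do.call(rbind, lapply(seq_along(chain_specs), function(i) {
    a <- moltypes[[chain_specs[i]]]
    a$chain <- chain_label(i)
    a
  }))
  atoms$index <- seq_len(nrow(atoms))
  atoms <- atoms[, c("index", "chain", "resseq", "resname", "atom")]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 chains = vapply(seq_along(chain_specs), chain_label, ""),
                 key = paste(atoms$chain, atoms$resseq, atoms$atom),
                 notes = notes),
            class = "topology_index")
}

#' @export
print.topology_index <- function(x, ...) {
  cat(sprintf("GROMACS topology index: %d atoms in %d chain(s)\n",
              nrow(x$atoms), length(x$chains)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Resolve a force-field atom name to its global topology index
#'
#' A miss is a value, not an error: restraints whose atoms do not resolve
#' (for example HD1 on a histidine modeled as the epsilon tautomer) are
#' skipped later with a warning.  Matching is by chain, residue sequence
#' number and atom name; residue-name disagreements (HIS vs HISE/HSD) do
#' not block a match but are reported in the miss reason when the atom
#' name itself is absent.
#'
#' @param topology A `"topology_index"`.
#' @param chain Chain label ("A", "B", ...).
#' @param resseq Residue sequence number.
#' @param atom Force-field atom name (already translated).
#' @return A list with `index` (integer or `NA`) and `reason`
#'   (`NA` on a hit).
#' @export
resolve_atom <- function(topology, chain, resseq, atom) {
  atom <- normalize_id(atom)
  hit <- match(paste(chain, resseq, atom), topology$key)
  if (!is.na(hit))
    return(list(index = topology$atoms$index[hit], reason = NA_character_))
  at_res <- topology$atoms$chain == chain & topology$atoms$resseq == resseq
  if (!any(at_res))
    return(list(index = NA_integer_,
                reason = sprintf("residue %s:%s not in topology",
                                 chain, resseq)))
  list(index = NA_integer_,
       reason = sprintf("atom %s not found in %s %s:%s", atom,
                        topology$atoms$resname[which(at_res)[1]],
                        chain, resseq))
}
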