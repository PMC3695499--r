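## structure_io: reading, validating and writing PDB-format RNA structures.
## Record-level parsing is delegated to bio3d; normalization (atom-name
## dialects, altLoc resolution, MODEL selection, hydrogen/HETATM filters)
## happens here.

CENTER_ATOM_CHOICES <- c("C1'", "P", "O5'", "O3'")
NUCLEOTIDE_NAMES <- c("A", "C", "G", "U")

new_rna_structure <- function(atoms, id, source_path = NA_character_,
                              model_index = 1L) {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_path = source_path,
                 model_index = as.integer(model_index)),
            class = "rna_structure")
}

#' Residue keys of a structure
#'
#' Residue identity is (chain, residue number, insertion code), rendered as
#' \code{"chain:number[icode]"}, in file order. PDB numbering is preserved
#' verbatim, never renumbered.
#'
#' @param structure An \code{rna_structure}.
#' @return Character vector of residue keys in file order.
#' @export
residue_keys <- function(structure) {
  unique(structure$atoms$res_key)
}

make_res_key <- function(chain, resno, insert) {
  paste0(chain, ":", resno, ifelse(insert == "", "", insert))
}

make_atom_key <- function(chain, resno, insert, elety) {
  paste(chain, resno, insert, elety, sep = "|")
}

## Normalize an atom name: strip whitespace, map the legacy PDB dialect
## character `*` to the prime `'` (C1* -> C1').
normalize_atom_name <- function(name) {
  gsub("*", "'", trimws(name), fixed = TRUE)
}

infer_hydrogen <- function(elety, elesy) {
  h <- !is.na(elesy) & toupper(trimws(elesy)) == "H"
  ## old files lack the element column: fall back to the name
  ## (H5', 1H2' and friends all start with H after leading digits)
  noel <- is.na(elesy) | trimws(elesy) == ""
  h[noel] <- grepl("^[0-9]*H", elety[noel])
  h
}

#' Read an RNA structure from a PDB file
#'
#' Parses one MODEL block of a PDB file into the package's structure
#' container. Atom names are normalized (\code{*} becomes \code{'}),
#' alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by altLoc letter), and hydrogens and HETATM records are
#' excluded unless requested.
#'
#' @param path Path to a PDB file.
#' @param id Structure label; defaults to the file name without extension.
#' @param model_index Which MODEL block to read (1-based; default first).
#' @param include_hydrogens Keep hydrogen atoms? Default \code{FALSE}:
#'   predicted models frequently omit hydrogens, and an asymmetric set
#'   would corrupt the atom correspondence.
#' @param include_hetero Keep HETATM records (ions, waters, ligands)?
#'   Default \code{FALSE}.
#' @return An object of class \code{rna_structure}: a list with an
#'   \code{atoms} data frame (one row per atom, with coordinates in
#'   Angstrom), the structure \code{id}, \code{source_path} and
#'   \code{model_index}.
#' @export
read_structure <- function(path, id = NULL, model_index = 1L,
                           include_hydrogens = FALSE,
                           include_hetero = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_io("cannot read PDB file: %s", as.character(path)[1])
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      stop_data("malformed PDB record (bad coordinate or numeric field) in %s: %s",
                path, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L || !any(at$type == "ATOM"))
    stop_data("no ATOM records in %s", path, class = "rnasphere_empty_structure")

  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model_index <- as.integer(model_index)
  if (model_index < 1L || model_index > n_models)
    stop_data("model_index %d out of range: file has %d MODEL block(s)",
              model_index, n_models)
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop_data("malformed coordinate field at ATOM record %s (file %s)",
              paste(at$eleno[bad], collapse = ", "), path)

  atoms <- data.frame(
    eleno  = as.integer(at$eleno),
    elety  = normalize_atom_name(at$elety),
    elesy  = ifelse(is.na(at$elesy), "", trimws(at$elesy)),
    alt    = ifelse(is.na(at$alt), "", at$alt),
    chain  = ifelse(is.na(at$chain), "", at$chain),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid  = trimws(at$resid),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$hydrogen <- infer_hydrogen(atoms$elety, atoms$elesy)

  if (!include_hetero)    atoms <- atoms[!atoms$hetero, , drop = FALSE]
  if (!include_hydrogens) atoms <- atoms[!atoms$hydrogen, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop_data("structure is empty after filtering: %s", path,
              class = "rnasphere_empty_structure")

  ## altLoc resolution: keep the highest-occupancy conformer per
  ## (residue, atom name); ties broken by altLoc letter order. Only
  ## groups that actually carry altLoc codes are resolved — duplicate
  ## keys without altLocs are a file defect that validate() must still
  ## be able to see. File order is preserved.
  key <- make_atom_key(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) {
    keep <- rep(TRUE, nrow(atoms))
    for (g in split(seq_len(nrow(atoms)), key)) {
      if (length(g) > 1L && any(atoms$alt[g] != "")) {
        best <- g[order(-atoms$o[g], atoms$alt[g])][1]
        keep[setdiff(g, best)] <- FALSE
        atoms$alt[best] <- ""
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
  } else {
    atoms$alt <- ""
  }

  atoms$res_key <- make_res_key(atoms$chain, atoms$resno, atoms$insert)
  atoms$atom_key <- make_atom_key(atoms$chain, atoms$resno, atoms$insert,
                                  atoms$elety)
  id <- id %||% tools::file_path_sans_ext(basename(path))
  new_rna_structure(atoms, id = id, source_path = path,
                    model_index = model_index)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("rna_structure '%s': %d residues, %d atoms (model %d)\n",
              x$id, length(residue_keys(x)), nrow(x$atoms), x$model_index))
  invisible(x)
}

coords_matrix <- function(structure, idx = NULL) {
  a <- structure$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Validate a parsed structure
#'
#' Checks the parsed hierarchy for inconsistencies and reports all of them
#' rather than failing on the first: duplicate residue identities (error),
#' residues missing a sphere-center candidate atom (warning), residue
#' names that are not standard nucleotides (warning), and breaks in the
#' residue numbering of a chain (warning).
#'
#' @param structure An \code{rna_structure}.
#' @param center_atoms Atom names checked for presence in every residue.
#' @return A \code{validation_report}: a data frame with columns
#'   \code{severity}, \code{code}, \code{message}, \code{locus}. An empty
#'   report means the structure passed every check (see
#'   \code{\link{is_clean}}).
#' @export
validate_structure <- function(structure,
                               center_atoms = CENTER_ATOM_CHOICES) {
  at <- structure$atoms
  issues <- list()
  add <- function(severity, code, message, locus) {
    issues[[length(issues) + 1L]] <<-
      data.frame(severity = severity, code = code, message = message,
                 locus = locus, stringsAsFactors = FALSE)
  }

  ## duplicate residue identity: same (chain, number, icode) appearing in
  ## two separate file blocks, or with conflicting residue names
  runs <- rle(at$res_key)$values
  for (k in unique(runs[duplicated(runs)]))
    add("error", "duplicate_residue",
        sprintf("residue key %s occurs in more than one block", k), k)
  for (k in residue_keys(structure)) {
    rn <- unique(at$resid[at$res_key == k])
    if (length(rn) > 1L)
      add("error", "duplicate_residue",
          sprintf("residue key %s carries multiple residue names (%s)",
                  k, paste(rn, collapse = ", ")), k)
  }

  ## per-residue checks
  for (k in residue_keys(structure)) {
    sub <- at[at$res_key == k, , drop = FALSE]
    for (ca in setdiff(center_atoms, sub$elety))
      add("warning", "missing_center_atom",
          sprintf("residue %s lacks center-atom candidate %s", k, ca), k)
    rn <- sub$resid[1]
    if (!rn %in% NUCLEOTIDE_NAMES)
      add("warning", "non_nucleotide",
          sprintf("residue %s has non-nucleotide name %s", k, rn), k)
  }

  ## chain breaks in numbering (only between residues without icodes)
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch & at$insert == "", , drop = FALSE]
    rn <- unique(sub$resno)
    jump <- which(diff(rn) > 1L)
    for (j in jump)
      add("warning", "chain_break",
          sprintf("chain %s numbering jumps from %d to %d",
                  ch, rn[j], rn[j + 1]),
          make_res_key(ch, rn[j], ""))
  }

  rep <- if (length(issues)) do.call(rbind, issues)
         else data.frame(severity = character(), code = character(),
                         message = character(), locus = character(),
                         stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Does a validation report contain no issues?
#' @param report A \code{validation_report}.
#' @return \code{TRUE} if no issue of any severity was found.
#' @export
is_clean <- function(report) nrow(report) == 0L

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation: clean (no issues)\n")
  } else {
    cat(sprintf("validation: %d issue(s) [%d error, %d warning]\n",
                nrow(x), sum(x$severity == "error"),
                sum(x$severity == "warning")))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$code[i], x$message[i]))
  }
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column ATOM/HETATM records (8.3 coordinate
#' fields). Reading the file back reproduces residue/atom keys exactly and
#' coordinates to PDB precision (0.001 Angstrom).
#'
#' @param structure An \code{rna_structure} with at least one atom.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  if (is.null(at) || nrow(at) == 0L)
    stop_data("refusing to write an empty structure",
              class = "rnasphere_empty_structure")
  tryCatch(
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(coords_matrix(structure))),
                     type = ifelse(at$hetero, "HETATM", "ATOM"),
                     resno = at$resno, resid = at$resid,
                     eleno = at$eleno, elety = at$elety,
                     chain = at$chain, insert = at$insert,
                     o = at$o, b = rep(0, nrow(at)),
                     elesy = at$elesy),
    error = function(e) stop_io("cannot write PDB to %s: %s", path,
                                conditionMessage(e)))
  invisible(path)
}
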