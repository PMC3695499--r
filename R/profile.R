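## profiles: sweep the radii vector over every nucleotide, aggregate the
## per-sphere RMSDs into the residue x radius matrix and the curves
## behind the averaged and cutoff plots.

DEFAULT_RADII <- c(3, 8, 20, 38, 300)

check_radii <- function(radii) {
  if (!is.numeric(radii) || length(radii) == 0L || anyNA(radii) ||
      any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop_usage("radii must be a non-empty, strictly increasing vector of positive values")
  as.numeric(radii)
}

#' Per-residue RMSD profile of a model against a reference
#'
#' For every nucleotide of the reference and every radius of the radii
#' vector, extracts the sphere neighborhood, superimposes the
#' corresponding model atoms and records the RMSD. Residues whose sphere
#' is undefined (missing center atom, fewer than 3 paired atoms) are
#' recorded as gaps (\code{NA}), never interpolated.
#'
#' @param reference,model \code{rna_structure} objects.
#' @param radii Strictly increasing vector of sphere radii in Angstrom.
#'   The default (3, 8, 20, 38, 300) moves from local backbone geometry
#'   to whole-molecule assessment.
#' @param center_atom Sphere center atom name (C1', P, O5' or O3').
#' @param mode \code{"all_atoms"} (every atom in the sphere) or
#'   \code{"center_atoms_only"} (only atoms of the chosen name).
#' @param model_id Label for the model; defaults to \code{model$id}.
#' @param correspondence Optional precomputed \code{\link{match_atoms}}
#'   result.
#' @return A \code{profile_matrix}: residue x radius matrices of RMSD
#'   \code{values} and \code{coverage}, a \code{reasons} matrix holding
#'   gap codes, the \code{residue_order} (reference file order) and
#'   \code{radii}.
#' @export
compute_profile <- function(reference, model, radii = DEFAULT_RADII,
                            center_atom = "C1'",
                            mode = c("all_atoms", "center_atoms_only"),
                            model_id = NULL, correspondence = NULL) {
  mode <- match.arg(mode)
  radii <- check_radii(radii)
  corr <- correspondence %||% match_atoms(reference, model)
  keys <- residue_keys(reference)
  nr <- length(keys); nc <- length(radii)
  dn <- list(keys, format(radii, trim = TRUE, scientific = FALSE))
  values <- matrix(NA_real_, nr, nc, dimnames = dn)
  coverage <- matrix(NA_real_, nr, nc, dimnames = dn)
  reasons <- matrix(NA_character_, nr, nc, dimnames = dn)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      res <- sphere_rmsd(reference, model, corr, keys[i], radii[j],
                         center_atom, mode)
      if (is_gap(res)) {
        reasons[i, j] <- res$reason
        coverage[i, j] <- res$coverage
      } else {
        values[i, j] <- res$rmsd
        coverage[i, j] <- res$coverage
      }
    }
  }
  structure(list(model_id = model_id %||% model$id,
                 residue_order = keys, radii = radii,
                 values = values, coverage = coverage, reasons = reasons,
                 center_atom = center_atom, mode = mode),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix '%s': %d residues x %d radii (%s), %d gap(s)\n",
              x$model_id, length(x$residue_order), length(x$radii),
              paste(x$radii, collapse = ", "), sum(is.na(x$values))))
  invisible(x)
}

#' Radius-averaged RMSD curve
#'
#' Arithmetic mean of the per-sphere RMSDs over all nucleotides with a
#' defined value, one mean per radius (unweighted over residues, not
#' atoms).
#'
#' @param profile A \code{profile_matrix}.
#' @return An \code{averaged_curve}: \code{mean_rmsd} and
#'   \code{n_defined} per radius; the mean is \code{NA} where no residue
#'   has a defined value.
#' @export
averaged_curve <- function(profile) {
  n_def <- colSums(!is.na(profile$values))
  means <- colMeans(profile$values, na.rm = TRUE)
  means[n_def == 0L] <- NA_real_
  structure(list(model_id = profile$model_id, radii = profile$radii,
                 mean_rmsd = unname(means), n_defined = unname(n_def)),
            class = "averaged_curve")
}

#' Cutoff curve: percent of nucleotides at or below a quality threshold
#'
#' For each radius, the percentage of nucleotides whose sphere RMSD is at
#' or below \code{threshold}, among nucleotides with a defined value.
#' The comparison is inclusive, so a self-comparison scores 100 percent
#' at any positive threshold.
#'
#' @param profile A \code{profile_matrix}.
#' @param threshold Cutoff threshold in Angstrom (> 0).
#' @return A \code{cutoff_curve}: \code{percent_below} in [0, 100] per
#'   radius (\code{NA} where no residue is defined) and \code{n_defined}.
#' @export
cutoff_curve <- function(profile, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_usage("cutoff threshold must be a single positive value")
  def <- !is.na(profile$values)
  n_def <- colSums(def)
  pct <- 100 * colSums(profile$values <= threshold & def, na.rm = TRUE) /
    pmax(n_def, 1L)
  pct[n_def == 0L] <- NA_real_
  structure(list(model_id = profile$model_id, threshold = threshold,
                 radii = profile$radii, percent_below = unname(pct),
                 n_defined = unname(n_def)),
            class = "cutoff_curve")
}

#' Write a profile matrix to CSV
#'
#' First column \code{residue} holds the key \code{"chain:number[icode]"};
#' one column per radius, labeled with the Angstrom value; gaps as empty
#' fields. Values are written with 17 significant digits so the file
#' round-trips losslessly through \code{\link{read_profile}}.
#'
#' @param profile A \code{profile_matrix}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_profile <- function(profile, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- paste(c("residue", sprintf("%.17g", profile$radii)),
                  collapse = ",")
  rows <- vapply(seq_along(profile$residue_order), function(i)
    paste(c(profile$residue_order[i], fmt(profile$values[i, ])),
          collapse = ","), character(1))
  tryCatch(writeLines(c(header, rows), path),
           error = function(e) stop_io("cannot write profile to %s: %s",
                                       path, conditionMessage(e)))
  invisible(path)
}

#' Read a profile matrix written by \code{\link{write_profile}}
#'
#' @param path CSV path.
#' @param model_id Label for the profile; defaults to the file name.
#' @return A \code{profile_matrix}. Coverage and gap-reason annotations
#'   are not stored in the CSV and come back as \code{NA}.
#' @export
read_profile <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop_io("no such profile file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L || names(df)[1] != "residue")
    stop_data("malformed profile header in %s: first column must be 'residue'",
              path)
  radii <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(radii))
    stop_data("malformed profile header in %s: non-numeric radius label",
              path)
  keys <- df$residue
  values <- as.matrix(df[, -1, drop = FALSE])
  values[values == ""] <- NA
  storage.mode(values) <- "double"
  dn <- list(keys, format(radii, trim = TRUE, scientific = FALSE))
  dimnames(values) <- dn
  structure(list(model_id = model_id %||%
                   tools::file_path_sans_ext(basename(path)),
                 residue_order = keys, radii = radii, values = values,
                 coverage = matrix(NA_real_, length(keys), length(radii),
                                   dimnames = dn),
                 reasons = matrix(NA_character_, length(keys),
                                  length(radii), dimnames = dn),
                 center_atom = NA_character_, mode = NA_character_),
            class = "profile_matrix")
}
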