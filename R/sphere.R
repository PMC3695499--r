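## sphere_metrics: atom correspondence, sphere-neighborhood extraction,
## and per-sphere / whole-molecule RMSD after optimal superposition.

#' Match atoms between a reference and a model structure
#'
#' Atoms are paired by structural key (chain, residue number, insertion
#' code, atom name) after name normalization; PDB serial numbers are
#' ignored, since they are file-layout artifacts. Unmatched atoms on
#' either side are listed, never silently dropped.
#'
#' @param reference,model \code{rna_structure} objects sharing chain and
#'   residue numbering.
#' @return An \code{atom_correspondence}: \code{pairs} (data frame of
#'   reference/model row indices and keys), \code{unmatched_reference},
#'   \code{unmatched_model} (key vectors), and \code{model_of_ref}, a
#'   lookup from reference atom row to model atom row (NA if unmatched).
#' @export
match_atoms <- function(reference, model) {
  rk <- reference$atoms$atom_key
  mk <- model$atoms$atom_key
  m <- match(rk, mk)
  hit <- !is.na(m)
  if (!any(hit))
    stop_data(paste0("no atom of the model matches the reference: ",
                     "structures share no chain/residue numbering"),
              class = "rnasphere_correspondence_error")
  structure(list(
    pairs = data.frame(ref_idx = which(hit), model_idx = m[hit],
                       key = rk[hit], stringsAsFactors = FALSE),
    unmatched_reference = rk[!hit],
    unmatched_model = setdiff(mk, rk),
    model_of_ref = m),
    class = "atom_correspondence")
}

#' @export
print.atom_correspondence <- function(x, ...) {
  cat(sprintf("atom correspondence: %d pairs, %d unmatched in reference, %d in model\n",
              nrow(x$pairs), length(x$unmatched_reference),
              length(x$unmatched_model)))
  invisible(x)
}

## Gap marker: a sphere for which no RMSD is defined (missing center atom
## or too few paired atoms). Rendered as a break in plots, excluded from
## means and cutoff denominators.
sphere_gap <- function(residue_key, reason, coverage = NA_real_) {
  structure(list(gap = TRUE, residue_key = residue_key, reason = reason,
                 coverage = coverage),
            class = "sphere_gap")
}

#' Is this result a gap marker?
#' @param x Result of \code{\link{sphere_rmsd}} or \code{\link{extract_sphere}}.
#' @return \code{TRUE} for a gap marker.
#' @export
is_gap <- function(x) inherits(x, "sphere_gap")

#' Extract the sphere neighborhood of one nucleotide
#'
#' Collects every eligible reference atom whose Euclidean distance to the
#' chosen center atom of \code{residue_key} is at most \code{radius}
#' (closed ball, so the center atom is always a member). Atoms of all
#' chains and residues are eligible; in \code{center_atoms_only} mode,
#' eligibility is restricted to atoms named \code{center_atom}.
#'
#' @param reference An \code{rna_structure}.
#' @param residue_key Residue key (see \code{\link{residue_keys}}).
#' @param radius Sphere radius in Angstrom (> 0).
#' @param center_atom One of \code{"C1'"}, \code{"P"}, \code{"O5'"},
#'   \code{"O3'"}.
#' @param mode \code{"all_atoms"} or \code{"center_atoms_only"}.
#' @return A \code{sphere_neighborhood} (center coordinates, member atom
#'   row indices and keys), or a gap marker when the residue lacks the
#'   center atom.
#' @export
extract_sphere <- function(reference, residue_key, radius,
                           center_atom = "C1'",
                           mode = c("all_atoms", "center_atoms_only")) {
  mode <- match.arg(mode)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop_usage("radius must be a single positive number")
  at <- reference$atoms
  if (!residue_key %in% at$res_key)
    stop_data("residue %s not present in structure %s", residue_key,
              reference$id)
  ci <- which(at$res_key == residue_key & at$elety == center_atom)
  if (length(ci) == 0L)
    return(sphere_gap(residue_key, "missing_center_atom"))
  ci <- ci[1]
  center <- c(at$x[ci], at$y[ci], at$z[ci])
  eligible <- if (mode == "center_atoms_only") which(at$elety == center_atom)
              else seq_len(nrow(at))
  d2 <- (at$x[eligible] - center[1])^2 + (at$y[eligible] - center[2])^2 +
        (at$z[eligible] - center[3])^2
  members <- eligible[d2 <= radius^2]
  structure(list(residue_key = residue_key, center_coords = center,
                 member_idx = members, member_keys = at$atom_key[members],
                 radius = radius, center_atom = center_atom, mode = mode),
            class = "sphere_neighborhood")
}

#' Per-sphere RMSD between model and reference
#'
#' Builds the sphere neighborhood in the reference, intersects its member
#' atoms with the atom correspondence, superimposes the paired subsets
#' and returns the minimized RMSD together with the coverage (fraction of
#' sphere members that had model partners). All failure modes yield gap
#' markers with reason codes, never errors.
#'
#' @inheritParams extract_sphere
#' @param model The model \code{rna_structure}.
#' @param correspondence Result of \code{\link{match_atoms}}.
#' @return A \code{superposition} with \code{coverage} filled in, or a
#'   gap marker (\code{reason} one of \code{"missing_center_atom"},
#'   \code{"too_few_pairs"}).
#' @export
sphere_rmsd <- function(reference, model, correspondence, residue_key,
                        radius, center_atom = "C1'",
                        mode = c("all_atoms", "center_atoms_only")) {
  mode <- match.arg(mode)
  sph <- extract_sphere(reference, residue_key, radius, center_atom, mode)
  if (is_gap(sph)) return(sph)
  mo <- correspondence$model_of_ref[sph$member_idx]
  paired <- !is.na(mo)
  coverage <- mean(paired)
  if (sum(paired) < 3L)
    return(sphere_gap(residue_key, "too_few_pairs", coverage))
  res <- kabsch_superpose(coords_matrix(reference, sph$member_idx[paired]),
                          coords_matrix(model, mo[paired]))
  res$coverage <- coverage
  res
}

#' Whole-molecule RMSD after optimal superposition
#'
#' One superposition over all paired atoms (optionally restricted to the
#' chosen center-atom type). When a sphere radius reaches the extent of
#' the molecule, every per-residue sphere RMSD equals this value exactly:
#' the atom sets, and hence the fits, are identical.
#'
#' @inheritParams sphere_rmsd
#' @return A \code{superposition} with \code{coverage} = fraction of
#'   eligible reference atoms that had model partners.
#' @export
global_rmsd <- function(reference, model, correspondence,
                        center_atom = "C1'",
                        mode = c("all_atoms", "center_atoms_only")) {
  mode <- match.arg(mode)
  at <- reference$atoms
  eligible <- if (mode == "center_atoms_only") which(at$elety == center_atom)
              else seq_len(nrow(at))
  mo <- correspondence$model_of_ref[eligible]
  paired <- !is.na(mo)
  if (sum(paired) < 3L)
    stop_data("fewer than 3 paired atoms for global RMSD",
              class = "rnasphere_insufficient_atoms")
  res <- kabsch_superpose(coords_matrix(reference, eligible[paired]),
                          coords_matrix(model, mo[paired]))
  res$coverage <- mean(paired)
  res
}
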