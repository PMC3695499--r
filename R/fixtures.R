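## fixtures: seeded synthetic reference helices and controlled decoys.
## Geometry is idealized, not chemically accurate: the method under test
## is purely geometric, so plausible spacing is all that matters.

## per-residue atom offsets in the local helix frame
## (radial, tangential, axial), Angstrom; C1' sits exactly on the
## backbone cylinder so its geometry has a closed form
HELIX_ATOM_OFFSETS <- data.frame(
  name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
           "C3'", "O3'", "C2'", "O2'", "C1'", "N1"),
  radial     = c(1.9, 3.2, 1.2, 1.4, 1.8, 1.0, -0.3, 1.2, 1.6, 0.1, 0.4, 0, -1.4),
  tangential = c(-2.8, -3.3, -3.6, -1.7, -0.6, 0.5, 0.3, 1.8, 2.9, 2.2, 3.4, 0, 0.4),
  axial      = c(-1.6, -1.4, -2.4, -0.8, -0.1, 0.3, 0.5, 0.9, 0.4, 1.5, 2.1, 0, 0.3),
  element    = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "O", "C", "N"),
  stringsAsFactors = FALSE)

#' Generate a synthetic RNA-like helix
#'
#' Deterministic (seeded) pseudo-RNA single helix used as a reference
#' structure in tests and demonstrations. Residue i sits at axial height
#' \code{(i-1) * rise_per_residue} and phase \code{(i-1) *
#' twist_per_residue}; each atom of the residue is placed at a fixed
#' offset in the rotating local frame, with C1' exactly on the backbone
#' cylinder. Defaults approximate A-form RNA dimensions (rise 2.81
#' Angstrom, twist 32.7 degrees), giving consecutive C1'-C1' distances of
#' about 6 Angstrom. The seed only draws the base sequence; geometry is
#' fully deterministic.
#'
#' @param n_residues Number of nucleotides (>= 1).
#' @param rise_per_residue Axial rise per residue, Angstrom.
#' @param twist_per_residue Helical twist per residue, degrees.
#' @param backbone_radius Radius of the C1' cylinder, Angstrom.
#' @param atoms_per_residue Atom names to emit; must include all four
#'   sphere-center candidates (C1', P, O5', O3').
#' @param seed Integer seed (base-sequence draw).
#' @param chain_id Chain identifier.
#' @param id Structure label.
#' @return An \code{rna_structure} that validates cleanly.
#' @export
generate_helix <- function(n_residues = 20, rise_per_residue = 2.81,
                           twist_per_residue = 32.7,
                           backbone_radius = 9.4,
                           atoms_per_residue = HELIX_ATOM_OFFSETS$name,
                           seed = 1, chain_id = "A",
                           id = sprintf("helix%d", n_residues)) {
  if (n_residues < 1 || rise_per_residue <= 0 || backbone_radius <= 0)
    stop_usage("helix parameters must be positive and n_residues >= 1")
  missing_centers <- setdiff(CENTER_ATOM_CHOICES, atoms_per_residue)
  if (length(missing_centers))
    stop_usage("atoms_per_residue must include every center-atom candidate; missing: %s",
               paste(missing_centers, collapse = ", "))
  off <- HELIX_ATOM_OFFSETS[match(atoms_per_residue, HELIX_ATOM_OFFSETS$name), ]
  if (anyNA(off$name))
    stop_usage("unknown atom name(s) in atoms_per_residue: %s",
               paste(setdiff(atoms_per_residue, HELIX_ATOM_OFFSETS$name),
                     collapse = ", "))
  seq_bases <- with_seed(seed,
    sample(NUCLEOTIDE_NAMES, n_residues, replace = TRUE))

  na <- nrow(off)
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    phi <- (i - 1) * twist_per_residue * pi / 180
    u <- c(cos(phi), sin(phi), 0)          # radial unit
    tg <- c(-sin(phi), cos(phi), 0)        # tangential unit
    z0 <- (i - 1) * rise_per_residue
    xyz <- t(vapply(seq_len(na), function(k)
      (backbone_radius + off$radial[k]) * u + off$tangential[k] * tg +
        c(0, 0, z0 + off$axial[k]),
      numeric(3)))
    rows[[i]] <- data.frame(
      eleno = (i - 1L) * na + seq_len(na),
      elety = off$name, elesy = off$element, alt = "",
      chain = chain_id, resno = i, insert = "",
      resid = seq_bases[i],
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = 1, hetero = FALSE, hydrogen = FALSE,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$res_key <- make_res_key(atoms$chain, atoms$resno, atoms$insert)
  atoms$atom_key <- make_atom_key(atoms$chain, atoms$resno, atoms$insert,
                                  atoms$elety)
  new_rna_structure(atoms, id = id)
}

## Rodrigues rotation about a unit axis by angle (radians)
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Perturb a structure into a controlled decoy
#'
#' Seeded, reproducible decoy generation emulating typical model-error
#' modes: whole-molecule rigid motion (which sphere RMSD must ignore),
#' i.i.d. Gaussian coordinate noise, displacement of selected residues,
#' rotation of a contiguous segment about a hinge, and deletion of named
#' atoms. All kinds preserve residue/atom keys except
#' \code{atom_deletion}, which only removes atoms.
#'
#' @param structure An \code{rna_structure}.
#' @param kind One of \code{"gaussian_noise"} (magnitude = per-coordinate
#'   sigma, Angstrom), \code{"residue_displacement"} (magnitude =
#'   displacement length, Angstrom, seeded random direction),
#'   \code{"segment_rotation"} (magnitude = angle in degrees about a
#'   seeded random axis through the first target residue's centroid),
#'   \code{"rigid_motion"} (seeded random proper rotation of the whole
#'   molecule plus a translation of length = magnitude), or
#'   \code{"atom_deletion"} (remove atoms named in \code{atoms} from the
#'   target residues).
#' @param magnitude Perturbation size (Angstrom or degrees; see
#'   \code{kind}).
#' @param target Residue keys or residue numbers to perturb;
#'   \code{NULL} means all residues. A target matching nothing is an
#'   error.
#' @param atoms For \code{atom_deletion}: atom names to remove.
#' @param seed Integer seed.
#' @return A new \code{rna_structure} (id suffixed with the kind).
#' @export
perturb_structure <- function(structure,
                              kind = c("gaussian_noise",
                                       "residue_displacement",
                                       "segment_rotation", "rigid_motion",
                                       "atom_deletion"),
                              magnitude = 0, target = NULL, atoms = NULL,
                              seed = 1) {
  kind <- match.arg(kind)
  at <- structure$atoms
  if (is.null(target)) {
    mask <- rep(TRUE, nrow(at))
  } else if (is.numeric(target)) {
    mask <- at$resno %in% target
  } else {
    mask <- at$res_key %in% target
  }
  if (!any(mask)) stop_usage("perturbation target matches no residue")

  with_seed(seed, {
    if (kind == "gaussian_noise") {
      n <- sum(mask)
      at$x[mask] <- at$x[mask] + stats::rnorm(n, 0, magnitude)
      at$y[mask] <- at$y[mask] + stats::rnorm(n, 0, magnitude)
      at$z[mask] <- at$z[mask] + stats::rnorm(n, 0, magnitude)
    } else if (kind == "residue_displacement") {
      shift <- magnitude * random_unit_vector()
      at$x[mask] <- at$x[mask] + shift[1]
      at$y[mask] <- at$y[mask] + shift[2]
      at$z[mask] <- at$z[mask] + shift[3]
    } else if (kind == "segment_rotation") {
      first_key <- at$res_key[mask][1]
      hinge <- colMeans(at[at$res_key == first_key, c("x", "y", "z")])
      R <- rotation_about_axis(random_unit_vector(), magnitude * pi / 180)
      xyz <- as.matrix(at[mask, c("x", "y", "z")])
      xyz <- sweep(sweep(xyz, 2, hinge) %*% t(R), 2, hinge, `+`)
      at$x[mask] <- xyz[, 1]; at$y[mask] <- xyz[, 2]; at$z[mask] <- xyz[, 3]
    } else if (kind == "rigid_motion") {
      R <- rotation_about_axis(random_unit_vector(),
                               stats::runif(1, 0, 2 * pi))
      shift <- magnitude * random_unit_vector()
      xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
      at$x <- xyz[, 1] + shift[1]
      at$y <- xyz[, 2] + shift[2]
      at$z <- xyz[, 3] + shift[3]
    } else if (kind == "atom_deletion") {
      if (is.null(atoms) || length(atoms) == 0L)
        stop_usage("atom_deletion requires the 'atoms' argument")
      drop <- mask & at$elety %in% atoms
      at <- at[!drop, , drop = FALSE]
      if (nrow(at) == 0L)
        stop_data("atom_deletion removed every atom",
                  class = "rnasphere_empty_structure")
    }
  })
  new_rna_structure(at, id = paste0(structure$id, "_", kind),
                    source_path = structure$source_path,
                    model_index = structure$model_index)
}
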