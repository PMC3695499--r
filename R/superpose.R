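## Optimal rigid-body superposition (Kabsch/McLachlan) via SVD of the
## covariance matrix, with determinant-sign correction so the returned
## rotation is always proper (no reflections), even when the reflected
## fit would score lower.

#' Optimally superimpose two paired coordinate sets
#'
#' Finds the proper rotation and translation that minimize the RMSD
#' between a moving coordinate set and a reference set, pairing rows
#' positionally. The algorithm subtracts centroids, takes the SVD of the
#' 3x3 covariance matrix and corrects the sign of the smallest singular
#' direction so that the rotation has determinant +1.
#'
#' @param ref_coords n x 3 matrix of reference coordinates (Angstrom).
#' @param mov_coords n x 3 matrix of moving (model) coordinates, row i
#'   paired with row i of \code{ref_coords}. At least 3 pairs required.
#' @return A \code{superposition}: list with \code{rotation} (3x3 proper
#'   rotation), \code{translation} (length-3), \code{rmsd} (Angstrom),
#'   \code{n_atoms}, \code{degenerate} (TRUE when either centered set has
#'   rank < 3, i.e. collinear or coplanar points) and \code{coverage}
#'   (NA here; filled by sphere-level callers). The fitted model
#'   coordinates are \code{mov \%*\% t(rotation) + translation}.
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref_coords <- as.matrix(ref_coords)
  mov_coords <- as.matrix(mov_coords)
  if (ncol(ref_coords) != 3L || ncol(mov_coords) != 3L)
    stop_usage("coordinate sets must be n x 3 matrices")
  n <- nrow(ref_coords)
  if (nrow(mov_coords) != n)
    stop_usage("coordinate sets differ in length (%d vs %d)",
               n, nrow(mov_coords))
  if (n < 3L)
    stop_data("superposition needs at least 3 atom pairs, got %d", n,
              class = "rnasphere_insufficient_atoms")
  if (!all(is.finite(ref_coords)) || !all(is.finite(mov_coords)))
    stop_data("non-finite coordinates in superposition input")

  cr <- colMeans(ref_coords)
  cm <- colMeans(mov_coords)
  Q <- sweep(ref_coords, 2L, cr)
  P <- sweep(mov_coords, 2L, cm)

  ## bit-identical inputs fit themselves exactly: return the identity
  ## transform rather than the ~1e-15 noise floor of the SVD route, so
  ## that self-comparisons are zero to full floating-point agreement
  if (all(mov_coords == ref_coords)) {
    rank_tol <- function(M) {
      sv <- svd(M, nu = 0, nv = 0)$d
      sum(sv > max(sv[1], 1e-12) * 1e-8)
    }
    return(structure(list(rotation = diag(3),
                          translation = c(0, 0, 0),
                          rmsd = 0, n_atoms = n,
                          degenerate = rank_tol(Q) < 3L,
                          coverage = NA_real_),
                     class = "superposition"))
  }

  H <- crossprod(P, Q)                       # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # proper rotation, det = +1

  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))

  ## rank deficiency of either point cloud (collinear/coplanar sets):
  ## the fit is still defined, but flagged for the caller
  rank_tol <- function(M) {
    sv <- svd(M, nu = 0, nv = 0)$d
    sum(sv > max(sv[1], 1e-12) * 1e-8)
  }
  degenerate <- rank_tol(Q) < 3L || rank_tol(P) < 3L

  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, n_atoms = n,
                 degenerate = degenerate,
                 coverage = NA_real_),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: RMSD %.4f A%s%s\n",
              x$n_atoms, x$rmsd,
              if (isTRUE(x$degenerate)) " [degenerate point set]" else "",
              if (!is.na(x$coverage)) sprintf(" (coverage %.2f)", x$coverage)
              else ""))
  invisible(x)
}
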