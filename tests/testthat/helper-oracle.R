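## Independent brute-force superposition oracle: minimizes RMSD over a
## hierarchical axis-angle rotation grid (final step well below 0.5
## degrees), after centroid subtraction. Shares no code with
## kabsch_superpose(); rotations are built from the Rodrigues formula.

.oracle_rot <- function(theta, phi, alpha) {
  a <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  ca <- cos(alpha); sa <- sin(alpha)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}

## stack of rotation matrices for a (theta, phi, alpha) grid -> 3K x 3,
## built from the closed-form Rodrigues elements
## R = cos(a) I + sin(a) [axis]_x + (1 - cos(a)) axis axis^T
.oracle_stack <- function(thetas, phis, alphas) {
  grid <- expand.grid(theta = thetas, phi = phis, alpha = alphas)
  ax <- sin(grid$theta) * cos(grid$phi)
  ay <- sin(grid$theta) * sin(grid$phi)
  az <- cos(grid$theta)
  s <- sin(grid$alpha); c <- cos(grid$alpha); v <- 1 - c
  K <- nrow(grid)
  stack <- matrix(0, 3L * K, 3L)
  r1 <- seq(1L, 3L * K, by = 3L)
  stack[r1, ]     <- cbind(c + v * ax^2, -s * az + v * ax * ay,
                           s * ay + v * ax * az)
  stack[r1 + 1L, ] <- cbind(s * az + v * ax * ay, c + v * ay^2,
                            -s * ax + v * ay * az)
  stack[r1 + 2L, ] <- cbind(-s * ay + v * ax * az, s * ax + v * ay * az,
                            c + v * az^2)
  list(grid = grid, stack = stack)
}

## evaluate all rotations of a stack at once; returns rmsd per rotation
.oracle_eval <- function(stackobj, P, Q) {
  n <- nrow(P)
  K <- nrow(stackobj$stack) / 3L
  A <- stackobj$stack %*% t(P)                 # 3K x n
  Qs <- t(Q)[rep(1:3, K), , drop = FALSE]
  ss <- colSums(matrix(rowSums((A - Qs)^2), nrow = 3L))
  sqrt(ss / n)
}

## shared coarse grid (10 degree steps), built once per test run
.oracle_coarse <- local({
  step <- 10 * pi / 180
  .oracle_stack(seq(0, pi, by = step),
                seq(0, 2 * pi - step, by = step),
                seq(0, pi, by = step))
})

## Brute-force minimum RMSD between mov and ref over rotations
## (translations removed by centering). Coarse 10-degree sweep of the
## whole rotation space; the several best coarse candidates are each
## refined on shrinking local grids down to ~0.016 degree steps, and the
## overall minimum wins. Multiple starting candidates guard against the
## rugged local-minimum structure RMSD has over SO(3) for small sets.
oracle_min_rmsd <- function(ref, mov, n_starts = 24L) {
  Q <- sweep(as.matrix(ref), 2, colMeans(ref))
  P <- sweep(as.matrix(mov), 2, colMeans(mov))
  r <- .oracle_eval(.oracle_coarse, P, Q)

  ## starting candidates: best coarse points, kept mutually distant in
  ## parameter space so several basins are explored
  ord <- order(r)
  starts <- integer(0)
  g <- .oracle_coarse$grid
  for (i in ord) {
    if (length(starts) >= n_starts) break
    far <- all(vapply(starts, function(s)
      sum((as.numeric(g[i, ]) - as.numeric(g[s, ]))^2), numeric(1)) >
        (20 * pi / 180)^2)
    if (length(starts) == 0L || far) starts <- c(starts, i)
  }

  best_r <- min(r)
  for (s in starts) {
    cand <- as.numeric(g[s, ])
    cand_r <- r[s]
    step <- 10 * pi / 180
    for (lev in 1:10) {
      step <- step / 2
      ## walk at this resolution until the minimum is interior to the
      ## +/-2-step window (prevents premature contraction at an edge)
      for (walk in 1:12) {
        local_grid <- .oracle_stack(cand[1] + (-2:2) * step,
                                    cand[2] + (-2:2) * step,
                                    cand[3] + (-2:2) * step)
        rr <- .oracle_eval(local_grid, P, Q)
        i <- which.min(rr)
        if (rr[i] < cand_r) {
          cand_r <- rr[i]
          cand <- as.numeric(local_grid$grid[i, ])
        }
        idx <- arrayInd(i, c(5L, 5L, 5L))
        if (all(idx > 1L & idx < 5L)) break
      }
    }
    best_r <- min(best_r, cand_r)
  }
  best_r
}
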