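## plots: headless renderers for the five standard views. Every renderer
## writes an image file and invisibly returns the structured series it
## plotted, so tests assert on data, never on pixels.

#' Deterministic per-model color palette
#' @param model_ids Character vector of model labels.
#' @return Named color vector, stable across runs for the same model list.
#' @export
model_palette <- function(model_ids) {
  n <- length(model_ids)
  cols <- grDevices::hcl.colors(max(n, 2L), palette = "Dark 3")[seq_len(n)]
  stats::setNames(cols, model_ids)
}

## blue (low RMSD, good) -> red (high RMSD, poor)
rmsd_colormap <- function(n = 100L) {
  grDevices::colorRampPalette(c("#2166AC", "#67A9CF", "#D1E5F0",
                                "#FDDBC7", "#EF8A62", "#B2182B"))(n)
}

open_plot_device <- function(path, width = 9, height = 6) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 110, type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    stop_usage("unsupported plot format '%s' (use png or svg)", ext)
  }
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "profile_matrix")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, logical(1),
                                       "profile_matrix")))
    stop_usage("expected one or more profile_matrix objects")
  profiles
}

radius_column <- function(profile, radius) {
  j <- match(TRUE, abs(profile$radii - radius) < 1e-9)
  if (is.na(j))
    stop_usage("radius %s not present in profile '%s'",
               format(radius), profile$model_id)
  j
}

#' Multi-model plot: per-residue RMSD at one fixed radius
#'
#' One curve per model over the nucleotide sequence order; gaps are
#' rendered as breaks in the polyline. The Y axis is auto-scaled to the
#' worst model so that all models share one scale.
#'
#' @param profiles A \code{profile_matrix} or list of them, sharing the
#'   reference residue order.
#' @param radius The sphere radius to display (must be in every profile).
#' @param path Output image path (.png or .svg).
#' @param main Optional title.
#' @return Invisibly: the plotted series (one numeric vector per model,
#'   \code{NA} at gaps), residue labels and the color assignment.
#' @export
plot_multi_model <- function(profiles, radius, path, main = NULL) {
  profiles <- as_profile_list(profiles)
  ro <- profiles[[1]]$residue_order
  for (p in profiles)
    if (!identical(p$residue_order, ro))
      stop_data("profiles do not share a residue order")
  series <- lapply(profiles, function(p) unname(p$values[, radius_column(p, radius)]))
  names(series) <- vapply(profiles, `[[`, character(1), "model_id")
  cols <- model_palette(names(series))
  ymax <- suppressWarnings(max(unlist(series), na.rm = TRUE))
  if (!is.finite(ymax)) ymax <- 1
  ymax <- max(ymax, 1e-3)

  open_plot_device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  x <- seq_along(ro)
  graphics::plot(NA, xlim = range(x), ylim = c(0, ymax * 1.05),
                 xlab = "Nucleotide (sequence order)", ylab = "RMSD [Å]",
                 main = main %||% sprintf("Per-residue RMSD, sphere radius %s Å",
                                          format(radius)))
  for (id in names(series))
    graphics::lines(x, series[[id]], col = cols[[id]], lwd = 2)
  graphics::legend("topright", legend = names(series), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(list(radius = radius, residues = ro, series = series,
                 colors = cols))
}

#' Averaged plot: mean sphere RMSD as a function of radius
#'
#' @param curves An \code{averaged_curve} or list of them sharing radii.
#' @param path Output image path.
#' @param log_x Plot the radius axis on a log scale (useful when the
#'   radii vector spans a whole-molecule radius such as 300 Angstrom).
#' @param main Optional title.
#' @return Invisibly: radii, per-model mean series, colors.
#' @export
plot_averaged <- function(curves, path, log_x = FALSE, main = NULL) {
  if (inherits(curves, "averaged_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, logical(1),
                                     "averaged_curve")))
    stop_usage("expected one or more averaged_curve objects")
  radii <- curves[[1]]$radii
  for (cv in curves)
    if (!isTRUE(all.equal(cv$radii, radii)))
      stop_data("averaged curves do not share a radii vector")
  series <- lapply(curves, `[[`, "mean_rmsd")
  names(series) <- vapply(curves, `[[`, character(1), "model_id")
  cols <- model_palette(names(series))
  ymax <- suppressWarnings(max(unlist(series), na.rm = TRUE))
  if (!is.finite(ymax)) ymax <- 1
  ymax <- max(ymax, 1e-3)

  open_plot_device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NA, xlim = range(radii), ylim = c(0, ymax * 1.05),
                 log = if (log_x) "x" else "",
                 xlab = "Sphere radius [Å]",
                 ylab = "Averaged RMSD [Å]",
                 main = main %||% "Averaged sphere RMSD")
  for (id in names(series)) {
    graphics::lines(radii, series[[id]], col = cols[[id]], lwd = 2)
    graphics::points(radii, series[[id]], col = cols[[id]], pch = 16)
  }
  graphics::legend("topleft", legend = names(series), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(list(radii = radii, series = series, colors = cols))
}

#' 2D map plot: residue x radius heat map of one model
#'
#' Blue encodes low RMSD (high prediction quality), red high RMSD. The
#' discrete radius rows are drawn as uniform-height bands, so the radii
#' need not be evenly spaced. Gaps appear in a neutral grey. Pass a
#' shared \code{zlim} (data range across all compared models) to make
#' maps comparable.
#'
#' @param profile A \code{profile_matrix}.
#' @param path Output image path.
#' @param zlim Color-scale limits; default = range of this profile.
#' @param main Optional title.
#' @return Invisibly: the value grid, the zlim used and the colormap.
#' @export
plot_2d_map <- function(profile, path, zlim = NULL, main = NULL) {
  v <- profile$values
  zl <- zlim %||% suppressWarnings(range(v, na.rm = TRUE))
  if (!all(is.finite(zl))) zl <- c(0, 1)
  if (zl[1] == zl[2]) zl[2] <- zl[1] + 1e-6

  open_plot_device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  nx <- nrow(v); ny <- ncol(v)
  graphics::plot(NA, xlim = c(0.5, nx + 0.5), ylim = c(0.5, ny + 0.5),
                 xlab = "Nucleotide (sequence order)",
                 ylab = "Sphere radius [Å]", yaxt = "n",
                 main = main %||% sprintf("RMSD map: %s", profile$model_id))
  graphics::rect(0.5, 0.5, nx + 0.5, ny + 0.5, col = "grey85", border = NA)
  graphics::image(x = seq_len(nx), y = seq_len(ny), z = v, zlim = zl,
                  col = rmsd_colormap(), add = TRUE)
  graphics::axis(2, at = seq_len(ny),
                 labels = format(profile$radii, trim = TRUE))
  invisible(list(values = v, zlim = zl, colormap = rmsd_colormap(),
                 radii = profile$radii))
}

#' 3D plot: residue x radius RMSD surface of one model
#'
#' Perspective surface of the profile grid with RMSD-colored facets
#' (same blue-to-red scale as the 2D map). Gap cells are rendered at the
#' grid minimum but stay \code{NA} in the returned data.
#'
#' @inheritParams plot_2d_map
#' @return Invisibly: the value grid and the zlim used.
#' @export
plot_3d_profile <- function(profile, path, zlim = NULL, main = NULL) {
  v <- profile$values
  zl <- zlim %||% suppressWarnings(range(v, na.rm = TRUE))
  if (!all(is.finite(zl))) zl <- c(0, 1)
  if (zl[1] == zl[2]) zl[2] <- zl[1] + 1e-6
  vfill <- v
  vfill[is.na(vfill)] <- zl[1]

  nx <- nrow(v); ny <- ncol(v)
  if (nx < 2L || ny < 2L)
    stop_usage("3D surface needs at least a 2 x 2 profile grid")
  ## facet color from the mean of its four corners
  facet <- (vfill[-1, -1] + vfill[-nx, -1] + vfill[-1, -ny] +
              vfill[-nx, -ny]) / 4
  pal <- rmsd_colormap()
  idx <- pmin(pmax(1L, as.integer(1 + (facet - zl[1]) /
                                    (zl[2] - zl[1]) * (length(pal) - 1))),
              length(pal))
  open_plot_device(path, width = 9, height = 7)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::persp(x = seq_len(nx), y = seq_len(ny), z = vfill,
                  col = pal[idx], theta = 40, phi = 25, expand = 0.6,
                  xlab = "Nucleotide", ylab = "Radius index",
                  zlab = "RMSD [A]", ticktype = "detailed",
                  main = main %||% sprintf("RMSD surface: %s",
                                           profile$model_id))
  invisible(list(values = v, zlim = zl, radii = profile$radii))
}

#' Cutoff plot: percent of nucleotides under the threshold, per radius
#'
#' One curve per model; the Y axis is fixed to [0, 100] percent. All
#' curves must share one threshold (mixing thresholds in a single plot
#' is an error) and one radii vector.
#'
#' @param curves A \code{cutoff_curve} or list of them.
#' @param path Output image path.
#' @param log_x Log-scale radius axis.
#' @param main Optional title.
#' @return Invisibly: radii, threshold, per-model percent series, colors.
#' @export
plot_cutoff <- function(curves, path, log_x = FALSE, main = NULL) {
  if (inherits(curves, "cutoff_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, logical(1),
                                     "cutoff_curve")))
    stop_usage("expected one or more cutoff_curve objects")
  thr <- curves[[1]]$threshold
  radii <- curves[[1]]$radii
  for (cv in curves) {
    if (!identical(cv$threshold, thr))
      stop_usage("all cutoff curves in one plot must share the threshold")
    if (!isTRUE(all.equal(cv$radii, radii)))
      stop_data("cutoff curves do not share a radii vector")
  }
  series <- lapply(curves, `[[`, "percent_below")
  names(series) <- vapply(curves, `[[`, character(1), "model_id")
  cols <- model_palette(names(series))

  open_plot_device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NA, xlim = range(radii), ylim = c(0, 100),
                 log = if (log_x) "x" else "",
                 xlab = "Sphere radius [Å]",
                 ylab = "Nucleotides at or below cutoff [%]",
                 main = main %||% sprintf("Cutoff plot (threshold %s Å)",
                                          format(thr)))
  for (id in names(series)) {
    graphics::lines(radii, series[[id]], col = cols[[id]], lwd = 2)
    graphics::points(radii, series[[id]], col = cols[[id]], pch = 16)
  }
  graphics::legend("bottomright", legend = names(series), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(list(radii = radii, threshold = thr, series = series,
                 colors = cols))
}
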