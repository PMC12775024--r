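#' PCA projection of feature matrices
#'
#' Centers the features and projects onto the leading principal components
#' (`F_reduced = (F - colmeans) %*% W_PCA`), components ordered by
#' decreasing explained variance. Signs are fixed deterministically: each
#' component is flipped so that its largest-magnitude loading is positive.
#'
#' @param features `n x d` numeric matrix (`n >= n_components`,
#'   `d >= n_components`).
#' @param n_components Number of components (2 by default, up to 3 for the
#'   component-wise scatter figures).
#' @param fitted_on Provenance tag recorded in the result (`"train"` or
#'   `"all"`).
#' @return A `pca_projection`: `w_pca` (`d x n_components`, orthonormal
#'   columns), `center`, `projected` (`n x n_components`),
#'   `explained_variance`, `explained_variance_ratio`, `fitted_on`.
#' @export
pca_fit_project <- function(features, n_components = 2L,
                            fitted_on = "all") {
  features <- as.matrix(features)
  n <- nrow(features); d <- ncol(features)
  if (n < n_components || d < n_components)
    stop_input("input error: need at least n_components rows and columns")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE,
                      rank. = as.integer(n_components))
  w <- pc$rotation
  flip <- vapply(seq_len(ncol(w)), function(j) {
    l <- w[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  w <- sweep(w, 2L, flip, "*")
  proj <- sweep(features, 2L, pc$center) %*% w
  structure(list(w_pca = unname(w), center = unname(pc$center),
                 projected = unname(proj),
                 explained_variance = unname(pc$sdev^2)[seq_len(n_components)],
                 explained_variance_ratio =
                   unname(pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
                 fitted_on = fitted_on),
            class = "pca_projection")
}

#' Project new features with a fitted PCA
#'
#' Applies a projection fitted on training features (see
#' [pca_fit_project()]) to further samples, avoiding leakage in figures.
#'
#' @param projection A `pca_projection`.
#' @param features `n x d` matrix with the same `d` as the fit.
#' @return `n x n_components` coordinate matrix.
#' @export
project_pca <- function(projection, features) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(projection$w_pca))
    stop_input("input error: feature dimension mismatch")
  sweep(features, 2L, projection$center) %*% projection$w_pca
}

#' Class-colored PCA scatter plot
#'
#' @param projection A `pca_projection` or an `n x >=2` coordinate matrix.
#' @param labels 0/1 labels of length `n`.
#' @param out_path PNG/SVG/PDF output path (format from the extension).
#' @param components Which two components to draw.
#' @return `out_path`, invisibly.
#' @export
scatter_by_class <- function(projection, labels, out_path,
                             components = c(1L, 2L)) {
  coords <- if (inherits(projection, "pca_projection"))
    projection$projected else as.matrix(projection)
  if (nrow(coords) != length(labels))
    stop_input("input error: labels length must match rows")
  df <- data.frame(x = coords[, components[1L]],
                   y = coords[, components[2L]],
                   class = factor(CLASS_NAMES[labels + 1L],
                                  levels = CLASS_NAMES))
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = class)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.6) +
    ggplot2::scale_colour_manual(values = c(FAW = "#c0392b",
                                            Healthy = "#27ae60")) +
    ggplot2::labs(x = paste("component", components[1L]),
                  y = paste("component", components[2L]),
                  colour = "class") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(out_path, gp, width = 5, height = 4, dpi = 150)
  invisible(out_path)
}

#' Weighted RGB/thermal blend for display
#'
#' `w_rgb * rgb + (1 - w_rgb) * thermal`, clipped to `[0, 1]`. The default
#' weight 0.6 emphasizes RGB colour detail while retaining thermal
#' information.
#'
#' @param rgb_01,thermal_01 Arrays of identical shape with values in
#'   `[0, 1]` (de-normalized for display).
#' @param w_rgb RGB weight in `[0, 1]`.
#' @return Blended array, same shape, clipped to `[0, 1]`.
#' @export
blend_for_display <- function(rgb_01, thermal_01, w_rgb = 0.6) {
  if (!identical(dim(rgb_01), dim(thermal_01)))
    stop_input("input error: shapes must match")
  clip01(w_rgb * rgb_01 + (1 - w_rgb) * thermal_01)
}

# "hot" colormap: black -> red -> yellow -> white on [0,1] intensities.
hot_colormap <- function(x) {
  x <- clip01(x)
  r <- clip01(3 * x)
  g <- clip01(3 * x - 1)
  b <- clip01(3 * x - 2)
  out <- array(0, c(dim(x), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  out
}

# (3,H,W) [0,1] tensor -> (H,W,3) display array.
chw_to_hwc <- function(x) aperm(x, c(2L, 3L, 1L))

#' Three-panel RGB / thermal / blended display
#'
#' Draws the de-normalized RGB image, the thermal image through a "hot"
#' colormap, and the 0.6/0.4 blend with the predicted class name
#' superimposed on the blended panel.
#'
#' @param pair A `preprocessed_pair` (its normalization stats are used to
#'   de-normalize for display).
#' @param prediction Predicted label (0/1) or a prediction list with
#'   `label`.
#' @param out_path PNG output path.
#' @return `out_path`, invisibly.
#' @export
triptych <- function(pair, prediction, out_path) {
  label <- if (is.list(prediction)) prediction$label[1L] else prediction[1L]
  rgb <- clip01(denormalize_image(pair$rgb, pair$stats_rgb))
  th <- clip01(denormalize_image(pair$thermal, pair$stats_thermal))
  rgb_d <- chw_to_hwc(rgb)
  th_int <- apply(chw_to_hwc(th), c(1L, 2L), mean)
  th_d <- hot_colormap(th_int)
  blend_d <- chw_to_hwc(blend_for_display(rgb, th))
  size <- dim(rgb_d)[1L]
  grDevices::png(out_path, width = 3L * size + 80L, height = size + 60L,
                 res = 96, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1L, 3L), mar = c(1, 1, 2, 1))
  titles <- c("RGB", "Thermal (hot)",
              paste0("Fused - predicted: ", CLASS_NAMES[label + 1L]))
  panels <- list(rgb_d, th_d, blend_d)
  for (i in 1:3) {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
    graphics::rasterImage(panels[[i]], 0, 0, 1, 1, interpolate = FALSE)
    graphics::title(main = titles[i], cex.main = 0.9)
  }
  # predicted class name on the blended (current) panel
  graphics::text(0.5, 0.06, CLASS_NAMES[label + 1L], col = "white",
                 cex = 1.4, font = 2L)
  invisible(out_path)
}
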