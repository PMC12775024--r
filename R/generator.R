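#' Configuration for the synthetic paired-image generator
#'
#' Describes a synthetic dataset of co-paired RGB (640x480) and thermal
#' (320x240) maize-leaf images whose class signal is deliberately split
#' across modalities: FAW pairs carry dark chewed-lesion blobs in RGB and
#' co-located warm hotspots in thermal, each cue independently suppressed
#' with its own probability so that neither modality alone suffices for all
#' pairs. Identical configurations (including `seed`) produce byte-identical
#' image files and manifests.
#'
#' @param n_pairs Number of image pairs (>= 2).
#' @param class_balance Fraction of FAW pairs in (0,1); the FAW count is
#'   `round(class_balance * n_pairs)`, the remainder Healthy.
#' @param rgb_size,thermal_size Integer `(width, height)` of the written
#'   rasters; defaults match the native 640x480 RGB / 320x240 thermal frames.
#' @param lesion_count_range Integer interval for the number of lesions on a
#'   FAW leaf.
#' @param hotspot_gain Dimensionless thermal contrast added at infested
#'   tissue, in [0,1] intensity units.
#' @param rgb_occlusion_prob Probability that a FAW pair's RGB lesion cue is
#'   suppressed (lesions not drawn), applied independently per pair.
#' @param thermal_degrade_prob Probability that a FAW pair's thermal hotspot
#'   cue is suppressed, independent of the RGB occlusion.
#' @param misalignment_px Maximum absolute per-axis translation (thermal
#'   pixels) between the lesion geometry and the thermal hotspots.
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian pixel
#'   noise, in [0,1] intensity units.
#' @param seed Integer seed driving every random choice.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pairs = 200L,
                             class_balance = 0.5,
                             rgb_size = c(640L, 480L),
                             thermal_size = c(320L, 240L),
                             lesion_count_range = c(3L, 7L),
                             hotspot_gain = 0.35,
                             rgb_occlusion_prob = 0.25,
                             thermal_degrade_prob = 0.25,
                             misalignment_px = 6L,
                             noise_sd = 0.05,
                             seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              class_balance = class_balance,
              rgb_size = as.integer(rgb_size),
              thermal_size = as.integer(thermal_size),
              lesion_count_range = as.integer(lesion_count_range),
              hotspot_gain = hotspot_gain,
              rgb_occlusion_prob = rgb_occlusion_prob,
              thermal_degrade_prob = thermal_degrade_prob,
              misalignment_px = as.integer(misalignment_px),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_pairs < 2L)
    stop_input("configuration error: n_pairs must be >= 2")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1)
    stop_input("configuration error: class_balance must be in (0,1)")
  n_faw <- round(cfg$class_balance * cfg$n_pairs)
  if (n_faw < 1L || n_faw >= cfg$n_pairs)
    stop_input("configuration error: class_balance leaves an empty class")
  if (any(cfg$rgb_size < 16L) || any(cfg$thermal_size < 16L))
    stop_input("configuration error: image sides must be >= 16 px")
  if (cfg$hotspot_gain < 0 || cfg$hotspot_gain > 1)
    stop_input("configuration error: hotspot_gain must lie in [0,1]")
  for (p in c("rgb_occlusion_prob", "thermal_degrade_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop_input("configuration error: ", p, " must lie in [0,1]")
  if (cfg$misalignment_px < 0)
    stop_input("configuration error: misalignment_px must be >= 0")
  invisible(cfg)
}

# Irregular-boundary ellipse rasterized into an HxW logical mask.
rasterize_lesion <- function(H, W, cx, cy, a, b, theta, wobble_freq,
                             wobble_phase, wobble_amp = 0.25) {
  rmax <- max(a, b) * (1 + wobble_amp) + 1
  i0 <- max(1L, floor(cy - rmax)); i1 <- min(H, ceiling(cy + rmax))
  j0 <- max(1L, floor(cx - rmax)); j1 <- min(W, ceiling(cx + rmax))
  mask <- matrix(FALSE, H, W)
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  r <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  mask[ii, jj] <- r <= 1 + wobble_amp * sin(wobble_freq * phi + wobble_phase)
  mask
}

# Low-frequency background field on an HxW grid (one draw of RNG params).
background_field <- function(H, W) {
  fx <- runif(1, 0.3, 1.2); fy <- runif(1, 0.3, 1.2)
  amp <- runif(1, 0.04, 0.09); phase <- runif(1, 0, 2 * pi)
  rows <- matrix(seq_len(H) / H, H, W)
  cols <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  amp * sin(2 * pi * (fx * cols + fy * rows) + phase)
}

# Nearest-neighbour downsample of an HxW logical mask to (th x tw), then
# integer translation by (dx, dy) thermal pixels with border clipping.
downsample_translate_mask <- function(mask, th, tw, dx = 0L, dy = 0L) {
  H <- nrow(mask); W <- ncol(mask)
  src_i <- pmin(H, pmax(1L, round((seq_len(th) - 0.5) * H / th + 0.5)))
  src_j <- pmin(W, pmax(1L, round((seq_len(tw) - 0.5) * W / tw + 0.5)))
  small <- mask[src_i, src_j, drop = FALSE]
  out <- matrix(FALSE, th, tw)
  ti <- seq_len(th) + dy; tj <- seq_len(tw) + dx
  keep_i <- ti >= 1L & ti <= th; keep_j <- tj >= 1L & tj <= tw
  out[ti[keep_i], tj[keep_j]] <- small[keep_i, keep_j, drop = FALSE]
  out
}

#' Generate a synthetic paired RGB/thermal dataset
#'
#' Writes `n_pairs` RGB and `n_pairs` thermal 8-bit 3-channel PNGs (thermal
#' is replicated grayscale), a `manifest.csv` with header
#' `pair_id,rgb_path,thermal_path,label` (paths relative to the manifest)
#' and a `ground_truth.json` holding run-length-encoded lesion/hotspot
#' masks, applied offsets, and corruption flags for every pair.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, a `faw_dataset` list with elements `samples` (the
#'   manifest data frame with paths resolved), `manifest`, `ground_truth`
#'   (file paths) and `config`.
#' @export
generate_dataset <- function(cfg, out_dir) {
  validate_generator_config(cfg)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop_input("configuration error: output directory not writable: ", out_dir)

  W <- cfg$rgb_size[1L]; H <- cfg$rgb_size[2L]
  tw <- cfg$thermal_size[1L]; th <- cfg$thermal_size[2L]
  n <- cfg$n_pairs
  n_faw <- as.integer(round(cfg$class_balance * n))

  rows <- vector("list", n)
  gt <- vector("list", n)

  with_seed(cfg$seed, {
    labels <- sample(c(rep(0L, n_faw), rep(1L, n - n_faw)))
    for (p in seq_len(n)) {
      pair_id <- sprintf("pair_%04d", p)
      label <- labels[p]

      # --- RGB frame -----------------------------------------------------
      base <- c(runif(1, 0.15, 0.30), runif(1, 0.45, 0.65),
                runif(1, 0.08, 0.20))
      field <- background_field(H, W)
      rgb <- array(0, c(H, W, 3L))
      for (ch in 1:3) rgb[, , ch] <- base[ch] + field

      lesion_mask <- matrix(FALSE, H, W)
      centroids <- NULL
      occluded <- FALSE; degraded <- FALSE; offset <- NULL
      sigmas <- numeric(0)

      if (label == 0L) {
        k <- sample(seq(cfg$lesion_count_range[1L],
                        cfg$lesion_count_range[2L]), 1L)
        centroids <- matrix(0, k, 2L, dimnames = list(NULL, c("cx", "cy")))
        masks <- vector("list", k)
        scale_min <- min(W, H)
        for (l in seq_len(k)) {
          cx <- runif(1, 0.15, 0.85) * W
          cy <- runif(1, 0.15, 0.85) * H
          # chewed feeding damage is conspicuous: semi-axes 6-12% of the
          # short frame side, for a total damaged area around 5-10%
          a <- runif(1, 0.06, 0.12) * scale_min
          b <- a * runif(1, 0.5, 1)
          theta <- runif(1, 0, pi)
          freq <- sample(3:6, 1L)
          ph <- runif(1, 0, 2 * pi)
          masks[[l]] <- rasterize_lesion(H, W, cx, cy, a, b, theta, freq, ph)
          centroids[l, ] <- c(cx, cy)
          sigmas[l] <- sqrt(a * b)
          lesion_mask <- lesion_mask | masks[[l]]
        }
        occluded <- runif(1) < cfg$rgb_occlusion_prob
        degraded <- runif(1) < cfg$thermal_degrade_prob
        m <- cfg$misalignment_px
        offset <- if (m > 0L) sample(seq(-m, m), 2L, replace = TRUE)
                  else c(0L, 0L)
        if (!occluded) {
          for (l in seq_len(k)) {
            col <- c(0.26, 0.16, 0.07) + runif(3, -0.03, 0.03)
            for (ch in 1:3) {
              plane <- rgb[, , ch]
              plane[masks[[l]]] <- col[ch]
              rgb[, , ch] <- plane
            }
          }
        }
      }
      rgb <- clip01(rgb + array(rnorm(H * W * 3L, 0, cfg$noise_sd),
                                c(H, W, 3L)))

      # --- thermal frame -------------------------------------------------
      tbase <- runif(1, 0.25, 0.40)
      tplane <- tbase + background_field(th, tw)
      hotspot_mask <- matrix(FALSE, th, tw)
      if (label == 0L) {
        hotspot_mask <- downsample_translate_mask(lesion_mask, th, tw,
                                                  offset[1L], offset[2L])
        if (!degraded) {
          trows <- matrix(seq_len(th), th, tw)
          tcols <- matrix(seq_len(tw), th, tw, byrow = TRUE)
          for (l in seq_len(nrow(centroids))) {
            tcx <- centroids[l, 1L] * tw / W + offset[1L]
            tcy <- centroids[l, 2L] * th / H + offset[2L]
            sg <- sigmas[l] * tw / W
            amp <- cfg$hotspot_gain * runif(1, 0.9, 1.1)
            tplane <- tplane + amp *
              exp(-((tcols - tcx)^2 + (trows - tcy)^2) / (2 * sg^2))
          }
        }
      }
      tplane <- clip01(tplane + matrix(rnorm(th * tw, 0, cfg$noise_sd),
                                       th, tw))
      thermal <- array(tplane, c(th, tw, 3L))

      rgb_rel <- file.path("images", paste0(pair_id, "_rgb.png"))
      th_rel <- file.path("images", paste0(pair_id, "_thermal.png"))
      png::writePNG(rgb, file.path(out_dir, rgb_rel))
      png::writePNG(thermal, file.path(out_dir, th_rel))

      rows[[p]] <- data.frame(pair_id = pair_id, rgb_path = rgb_rel,
                              thermal_path = th_rel, label = label,
                              stringsAsFactors = FALSE)
      gt[[p]] <- list(
        label = label,
        occluded = occluded,
        degraded = degraded,
        offset = if (is.null(offset)) NULL else as.integer(offset),
        lesion_centroids = if (is.null(centroids)) NULL else
          unname(round(centroids, 3)),
        lesion_mask = rle_encode_mask(lesion_mask),
        hotspot_mask = rle_encode_mask(hotspot_mask))
      names(gt)[p] <- pair_id
    }
  })

  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, manifest_path)
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  samples <- manifest
  samples$rgb_path <- file.path(out_dir, samples$rgb_path)
  samples$thermal_path <- file.path(out_dir, samples$thermal_path)
  samples$provenance <- "synthetic"
  invisible(structure(list(samples = samples, manifest = manifest_path,
                           ground_truth = gt_path, config = cfg),
                      class = "faw_dataset"))
}

#' Ground-truth record for one generated pair
#'
#' Returns the generator's per-pair ground truth: the binary lesion mask in
#' the RGB frame, the hotspot mask in the thermal frame (the lesion mask
#' downsampled and translated by the recorded offset), the applied offset,
#' and the corruption flags. Intended for tests and audits, not training.
#'
#' @param dataset A `faw_dataset` from [generate_dataset()], or the path of
#'   the directory it was written to.
#' @param pair_id Pair identifier, e.g. `"pair_0001"`.
#' @return A list with `label`, `occluded`, `degraded`, `offset`,
#'   `lesion_centroids`, and decoded logical matrices `lesion_mask`,
#'   `hotspot_mask`.
#' @export
generator_ground_truth <- function(dataset, pair_id) {
  gt_path <- if (inherits(dataset, "faw_dataset")) dataset$ground_truth
             else file.path(dataset, "ground_truth.json")
  if (!file.exists(gt_path))
    stop_input("lookup error: no ground truth at ", gt_path)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!pair_id %in% names(gt))
    stop_input("lookup error: unknown pair_id ", pair_id)
  rec <- gt[[pair_id]]
  rec$offset <- if (is.null(rec$offset)) NULL else
    as.integer(unlist(rec$offset))
  rec$lesion_mask <- rle_decode_mask(
    list(dims = unlist(rec$lesion_mask$dims),
         runs = unlist(rec$lesion_mask$runs)))
  rec$hotspot_mask <- rle_decode_mask(
    list(dims = unlist(rec$hotspot_mask$dims),
         runs = unlist(rec$hotspot_mask$runs)))
  rec
}
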