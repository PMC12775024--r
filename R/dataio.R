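#' Read a pairing manifest
#'
#' Reads a CSV manifest with header `pair_id,rgb_path,thermal_path,label`
#' (paths relative to the manifest's directory or absolute), validates every
#' row — both images must exist and decode to 3-channel rasters, the label
#' must be 0 (FAW) or 1 (Healthy) — and returns the samples in file order.
#'
#' @param path Manifest CSV path.
#' @param validate If `TRUE` (default), decode every referenced image to
#'   verify it is readable; pairing errors name the offending `pair_id`.
#' @return A data frame with columns `pair_id`, `rgb_path`, `thermal_path`
#'   (resolved paths), `label` (integer) and `provenance`.
#' @export
read_manifest <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop_input("missing manifest file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  want <- c("pair_id", "rgb_path", "thermal_path", "label")
  if (!identical(names(df), want))
    stop_input("parse error: manifest header must be ",
               paste(want, collapse = ","))
  if (anyNA(suppressWarnings(as.integer(df$label))) ||
      !all(df$label %in% c("0", "1")))
    stop_input("parse error: labels must be 0 (FAW) or 1 (Healthy)")
  df$label <- as.integer(df$label)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$rgb_path <- resolve(df$rgb_path)
  df$thermal_path <- resolve(df$thermal_path)
  for (i in seq_len(nrow(df))) {
    for (col in c("rgb_path", "thermal_path")) {
      f <- df[[col]][i]
      if (!file.exists(f))
        stop_input("pairing error for ", df$pair_id[i], ": missing ", col,
                   " (", f, ")")
      if (validate) load_image(f)
    }
  }
  df$provenance <- "external"
  df
}

#' Write a pairing manifest
#'
#' @param samples Data frame with columns `pair_id`, `rgb_path`,
#'   `thermal_path`, `label`; extra columns are dropped.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(samples, path) {
  utils::write.csv(
    samples[, c("pair_id", "rgb_path", "thermal_path", "label")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a raster image as a (H, W, 3) array in [0, 1]
#'
#' Reads PNG/JPEG/TIFF (8- or 16-bit) through EBImage; grayscale images are
#' replicated to 3 channels, alpha channels are dropped.
#'
#' @param path Image file path.
#' @return Numeric array `(height, width, 3)` with values in `[0, 1]`.
#' @export
load_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img) # EBImage convention: (x = width, y = height[, channel])
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3L] < 3L) a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
  aperm(a, c(2L, 1L, 3L))
}

#' Preprocessing configuration
#'
#' @param target_size Square canvas side in pixels (>= 16; default 224).
#' @param canvas_policy `"pad"` (default): scale by
#'   `target_size / max(w, h)` so the whole image fits, centre it, and fill
#'   the remainder with `pad_value`. `"center_crop"`: scale by
#'   `target_size / min(w, h)` and centre-crop the longer side.
#' @param pad_value Fill intensity in `[0, 1]` under the pad policy.
#' @param interpolation Resampling kernel; `"bilinear"` (default) or
#'   `"nearest"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 224L,
                              canvas_policy = c("pad", "center_crop"),
                              pad_value = 0,
                              interpolation = c("bilinear", "nearest")) {
  target_size <- as.integer(target_size)
  if (target_size < 16L)
    stop_input("configuration error: target_size must be >= 16")
  if (pad_value < 0 || pad_value > 1)
    stop_input("configuration error: pad_value must lie in [0,1]")
  structure(list(target_size = target_size,
                 canvas_policy = match.arg(canvas_policy),
                 pad_value = pad_value,
                 interpolation = match.arg(interpolation)),
            class = "preprocess_config")
}

#' Aspect-preserving resize onto a square canvas
#'
#' Scales an image by `scale_factor = target_size / max(w, h)` (pad policy;
#' `min` under centre-crop), with the new sides computed by integer
#' truncation `new_w = int(w * scale_factor)`, `new_h = int(h *
#' scale_factor)`, and centres the resized content on a `target_size` square
#' canvas. Under the pad policy remaining pixels take `pad_value`, so
#' `max(new_w, new_h) == target_size` and no content is discarded.
#'
#' @param image Numeric `(H, W, 3)` array in `[0, 1]`.
#' @param cfg A [preprocess_config()].
#' @return List with `image` — a `(3, target_size, target_size)` array — and
#'   `scale_factor`.
#' @export
resize_to_canvas <- function(image, cfg = preprocess_config()) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop_input("input error: image must be a (H, W, 3) array")
  h <- d[1L]; w <- d[2L]
  if (h < 1L || w < 1L) stop_input("input error: zero-sized image")
  t <- cfg$target_size
  sf <- if (cfg$canvas_policy == "pad") t / max(w, h) else t / min(w, h)
  new_w <- as.integer(w * sf) # truncation, int(w * scale_factor)
  new_h <- as.integer(h * sf)
  content <- if (new_w == w && new_h == h) image else {
    e <- EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
    filt <- if (cfg$interpolation == "bilinear") "bilinear" else "none"
    r <- EBImage::resize(e, w = new_w, h = new_h, filter = filt)
    aperm(as.array(r), c(2L, 1L, 3L))
  }
  if (cfg$canvas_policy == "pad") {
    canvas <- array(cfg$pad_value, c(t, t, 3L))
    top <- (t - new_h) %/% 2L
    left <- (t - new_w) %/% 2L
    canvas[top + seq_len(new_h), left + seq_len(new_w), ] <- content
  } else {
    top <- (new_h - t) %/% 2L
    left <- (new_w - t) %/% 2L
    canvas <- content[top + seq_len(t), left + seq_len(t), , drop = FALSE]
  }
  list(image = aperm(canvas, c(3L, 1L, 2L)), scale_factor = sf)
}

#' Per-channel normalization statistics
#'
#' @param mean,sd Numeric 3-vectors (per channel); all `sd` components must
#'   be strictly positive.
#' @param source `"vit_default"` or `"dataset_estimated"`.
#' @return A `norm_stats` list.
#' @export
norm_stats <- function(mean, sd, source = "dataset_estimated") {
  if (length(mean) != 3L || length(sd) != 3L)
    stop_input("configuration error: mean and sd must be 3-vectors")
  if (any(sd <= 0))
    stop_input("configuration error: all sd components must be > 0")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 source = source), class = "norm_stats")
}

#' Standard ViT channel statistics
#'
#' The ImageNet statistics used by pretrained vision transformers:
#' mean `(0.485, 0.456, 0.406)`, sd `(0.229, 0.224, 0.225)`.
#' @return A `norm_stats` object with `source = "vit_default"`.
#' @export
vit_norm_stats <- function() {
  norm_stats(c(0.485, 0.456, 0.406), c(0.229, 0.224, 0.225),
             source = "vit_default")
}

#' Per-channel affine normalization
#'
#' Applies `(image - mean) / sd` channelwise to a `(3, H, W)` array scaled
#' to `[0, 1]`. Invertible via [denormalize_image()].
#'
#' @param image `(3, H, W)` array.
#' @param stats A [norm_stats()].
#' @return Normalized array of the same shape.
#' @export
normalize_image <- function(image, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  d <- dim(image)
  if (length(d) != 3L || d[1L] != 3L)
    stop_input("input error: image must be a (3, H, W) array")
  (image - stats$mean) / stats$sd # recycles along the channel (first) axis
}

#' Inverse of [normalize_image()]
#' @inheritParams normalize_image
#' @return De-normalized array.
#' @export
denormalize_image <- function(image, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  image * stats$sd + stats$mean
}

#' Estimate thermal normalization statistics
#'
#' Per-channel mean and standard deviation pooled over all pixels of the
#' supplied thermal images — by contract the *training split only*, so no
#' test-set statistics leak into preprocessing. A constant channel
#' (`sd == 0`) is degenerate; its sd is replaced by 1.0 with a warning.
#'
#' @param images List of `(3, H, W)` arrays in `[0, 1]` (resized, not yet
#'   normalized).
#' @return A [norm_stats()] with `source = "dataset_estimated"`.
#' @export
estimate_thermal_stats <- function(images) {
  if (length(images) < 2L)
    stop_input("input error: need at least 2 images to estimate stats")
  mu <- numeric(3L); sg <- numeric(3L)
  for (ch in 1:3) {
    v <- unlist(lapply(images, function(x) as.numeric(x[ch, , ])))
    mu[ch] <- mean(v)
    sg[ch] <- stats::sd(v)
  }
  if (any(sg == 0)) {
    warning("constant thermal channel: sd = 0 replaced by 1.0",
            call. = FALSE)
    sg[sg == 0] <- 1.0
  }
  norm_stats(mu, sg, source = "dataset_estimated")
}

#' Preprocess one RGB/thermal pair
#'
#' Loads both images, resizes each onto the square canvas
#' ([resize_to_canvas()]) and normalizes channelwise.
#'
#' @param sample One manifest row (list or single-row data frame) with
#'   `pair_id`, `rgb_path`, `thermal_path`, `label`.
#' @param cfg A [preprocess_config()].
#' @param stats_rgb,stats_thermal [norm_stats()] for each modality.
#' @return A `preprocessed_pair` list: `rgb`, `thermal` (normalized
#'   `(3, t, t)` arrays), `label`, `pair_id`, `stats_rgb`, `stats_thermal`,
#'   `scale_factors`.
#' @export
preprocess_pair <- function(sample, cfg = preprocess_config(),
                            stats_rgb = vit_norm_stats(),
                            stats_thermal = vit_norm_stats()) {
  rgb <- resize_to_canvas(load_image(sample$rgb_path), cfg)
  th <- resize_to_canvas(load_image(sample$thermal_path), cfg)
  structure(list(
    rgb = normalize_image(rgb$image, stats_rgb),
    thermal = normalize_image(th$image, stats_thermal),
    label = as.integer(sample$label),
    pair_id = sample$pair_id,
    stats_rgb = stats_rgb, stats_thermal = stats_thermal,
    scale_factors = c(rgb = rgb$scale_factor, thermal = th$scale_factor)),
    class = "preprocessed_pair")
}

#' Load and resize every pair of a sample table (no normalization)
#'
#' The expensive half of preprocessing — decoding and resizing — separated
#' out so that repeated studies over the same dataset (e.g. several split
#' seeds) can reuse it; [preprocess_dataset()] accepts the result via its
#' `resized` argument.
#'
#' @param samples Manifest data frame (see [read_manifest()]).
#' @param cfg A [preprocess_config()].
#' @return A `resized_dataset` list: `rgb`, `thermal` (lists of
#'   `(3, t, t)` arrays in `[0, 1]`), `sf` (scale-factor matrix), `config`.
#' @export
resize_dataset <- function(samples, cfg = preprocess_config()) {
  n <- nrow(samples)
  rgb_r <- vector("list", n); th_r <- vector("list", n)
  sf <- matrix(0, n, 2L, dimnames = list(NULL, c("rgb", "thermal")))
  for (i in seq_len(n)) {
    r <- resize_to_canvas(load_image(samples$rgb_path[i]), cfg)
    t_ <- resize_to_canvas(load_image(samples$thermal_path[i]), cfg)
    rgb_r[[i]] <- r$image; th_r[[i]] <- t_$image
    sf[i, ] <- c(r$scale_factor, t_$scale_factor)
  }
  structure(list(rgb = rgb_r, thermal = th_r, sf = sf, config = cfg),
            class = "resized_dataset")
}

#' Preprocess a whole sample table
#'
#' Resizes every pair, estimates thermal statistics on the training subset
#' (all samples when `train_idx` is `NULL`), then normalizes RGB with the
#' ViT defaults and thermal with the estimated statistics.
#'
#' @param samples Manifest data frame (see [read_manifest()]).
#' @param cfg A [preprocess_config()].
#' @param stats_rgb RGB [norm_stats()]; ViT defaults unless overridden.
#' @param stats_thermal Thermal [norm_stats()], or `NULL` to estimate from
#'   the training subset.
#' @param train_idx Integer indices of the training rows used for
#'   estimation.
#' @param resized Optional [resize_dataset()] result for these samples,
#'   skipping the decode/resize work.
#' @return List with `pairs` (list of `preprocessed_pair`), `stats_rgb`,
#'   `stats_thermal`, and the `config`.
#' @export
preprocess_dataset <- function(samples, cfg = preprocess_config(),
                               stats_rgb = vit_norm_stats(),
                               stats_thermal = NULL,
                               train_idx = NULL, resized = NULL) {
  n <- nrow(samples)
  if (is.null(resized)) resized <- resize_dataset(samples, cfg)
  if (length(resized$rgb) != n ||
      !identical(resized$config$target_size, cfg$target_size))
    stop_input("input error: resized cache does not match samples/config")
  rgb_r <- resized$rgb; th_r <- resized$thermal; sf <- resized$sf
  if (is.null(stats_thermal)) {
    idx <- if (is.null(train_idx)) seq_len(n) else train_idx
    stats_thermal <- estimate_thermal_stats(th_r[idx])
  }
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pairs[[i]] <- structure(list(
      rgb = normalize_image(rgb_r[[i]], stats_rgb),
      thermal = normalize_image(th_r[[i]], stats_thermal),
      label = as.integer(samples$label[i]),
      pair_id = samples$pair_id[i],
      stats_rgb = stats_rgb, stats_thermal = stats_thermal,
      scale_factors = sf[i, ]), class = "preprocessed_pair")
  }
  list(pairs = pairs, stats_rgb = stats_rgb, stats_thermal = stats_thermal,
       config = cfg)
}
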