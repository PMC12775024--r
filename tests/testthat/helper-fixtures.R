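# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small generated dataset at reduced raster sizes (fast); cached by key.
small_dataset <- function(n_pairs = 12L, seed = 7L, key = NULL, ...) {
  key <- key %||% paste0("ds_", n_pairs, "_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- generator_config(n_pairs = n_pairs, seed = seed,
                          rgb_size = c(64L, 48L), thermal_size = c(32L, 24L),
                          ...)
  ds <- generate_dataset(cfg, file.path(tempdir(), key))
  .fixture_env[[key]] <- ds
  ds
}

# Preprocessed pairs of the small dataset at a small square canvas.
small_pairs <- function(target = 32L, n_pairs = 12L, seed = 7L) {
  key <- paste0("pp_", target, "_", n_pairs, "_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  ds <- small_dataset(n_pairs, seed)
  prep <- preprocess_dataset(ds$samples,
                             preprocess_config(target_size = target))
  .fixture_env[[key]] <- prep$pairs
  prep$pairs
}

# Linearly separable toy pairs: constant-shifted images per class plus a
# little noise, so mean intensity alone separates the classes.
separable_pairs <- function(n = 40L, size = 32L, seed = 99L) {
  stats <- norm_stats(c(0, 0, 0), c(1, 1, 1))
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    label <- as.integer(i > n / 2)
    shift <- if (label == 0L) 0.6 else -0.6
    structure(list(
      rgb = array(shift + rnorm(3 * size * size, 0, 0.1),
                  c(3L, size, size)),
      thermal = array(shift + rnorm(3 * size * size, 0, 0.1),
                      c(3L, size, size)),
      label = label, pair_id = sprintf("toy_%03d", i),
      stats_rgb = stats, stats_thermal = stats,
      scale_factors = c(rgb = 1, thermal = 1)),
      class = "preprocessed_pair")
  }))
}

# Brute-force metric oracle: recount every quantity from first principles.
oracle_metrics <- function(y_true, y_pred, positive = 0L) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == positive
    p_pos <- y_pred[i] == positive
    if (t_pos && p_pos) tp <- tp + 1L
    else if (!t_pos && p_pos) fp <- fp + 1L
    else if (t_pos && !p_pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       accuracy = (tp + tn) / length(y_true),
       precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# Mann-Whitney AUC oracle: P(score_pos > score_neg) + 0.5 P(equal),
# enumerated over all positive/negative pairs.
oracle_auc <- function(y_true, scores, positive = 0L) {
  sp <- scores[y_true == positive]
  sn <- scores[y_true != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

md5_of <- function(paths) unname(tools::md5sum(paths))

`%||%` <- function(a, b) if (is.null(a)) b else a
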