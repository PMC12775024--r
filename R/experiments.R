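#' Ablation run configuration
#'
#' Describes one ablation study: the data source (a [generator_config()] or
#' an existing manifest), the arms to run, the shared preprocessing size and
#' split, and the per-arm training recipes. A single `seed` fans out to the
#' data, split, and per-arm training seeds through a fixed schedule keyed by
#' arm *name*, so arm order never changes any arm's result.
#'
#' @param generator A [generator_config()] used to synthesize data (its
#'   `seed` is re-derived from `seed` below), or `NULL` when `manifest` is
#'   given.
#' @param manifest Path to an existing pairing manifest, or `NULL`.
#' @param arms Character vector from `rgb_only`, `thermal_only`,
#'   `no_fusion`, `fused_feature`, `fused_image`.
#' @param target_size Preprocessing canvas side (96 for desk-scale studies).
#' @param train Feature-path recipe: `learning_rate`, `epochs`,
#'   `batch_size`, `warmup_steps`. The desk-scale default (1e-3, 8 epochs of
#'   batch 16 with a 10-step warmup) compensates for the small step count of
#'   a 160-pair training split; see the methods vignette.
#' @param vit Image-path recipe for the `fused_image` arm: `learning_rate`,
#'   `weight_decay`, `epochs`, `batch_size` plus `vit_spec` overrides
#'   `embed_dim`, `depth`, `heads`, `mlp_ratio`.
#' @param train_fraction,stratified Shared 80/20 split settings.
#' @param seed Global seed.
#' @param out_dir Output directory for reports, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       manifest = NULL,
                       arms = c("rgb_only", "thermal_only", "no_fusion",
                                "fused_feature"),
                       target_size = 96L,
                       train = list(learning_rate = 1e-3, epochs = 8L,
                                    batch_size = 16L, warmup_steps = 10L),
                       vit = list(learning_rate = 1e-3, weight_decay = 0.01,
                                  epochs = 40L, batch_size = 16L,
                                  warmup_steps = 20L,
                                  embed_dim = 64L, depth = 2L, heads = 4L,
                                  mlp_ratio = 2L),
                       train_fraction = 0.8, stratified = TRUE,
                       seed = 11L, out_dir = NULL) {
  unknown <- setdiff(arms, arm_names())
  if (length(unknown))
    stop_input("configuration error: unknown arm ",
               paste(unknown, collapse = ", "))
  structure(list(generator = generator, manifest = manifest, arms = arms,
                 target_size = as.integer(target_size), train = train,
                 vit = vit, train_fraction = train_fraction,
                 stratified = stratified, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# Fixed per-arm seed schedule, keyed by name so arm order is irrelevant.
arm_seed <- function(seed, arm) {
  code <- match(arm, arm_names())
  derive_seed(seed, 1000L + code)
}

#' Run the ablation study
#'
#' Trains and evaluates every requested arm on one shared dataset, split
#' and preprocessing: `rgb_only` and `thermal_only` use a single extractor,
#' `no_fusion` feeds both modalities to one shared classifier without joint
#' feature learning (predictions averaged per pair), `fused_feature`
#' concatenates the two 256-vectors, and `fused_image` trains the 6-channel
#' ViT. Each arm's per-test-set metrics equal a standalone evaluation of the
#' same trained model.
#'
#' @param cfg A [run_config()].
#' @param resized Optional [resize_dataset()] cache matching the dataset,
#'   reused across replicated studies.
#' @return An `ablation_report`: `table` (one row per arm: accuracy,
#'   precision, recall, f1, auc), `reports` (named `metric_report`s),
#'   `models`, `split`, `seeds`, and the config echo.
#' @export
run_ablation <- function(cfg = run_config(), resized = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  data_dir <- NULL
  if (!is.null(cfg$manifest)) {
    # image decodability is re-checked by preprocessing just below
    samples <- read_manifest(cfg$manifest, validate = FALSE)
  } else {
    gen_cfg <- cfg$generator
    gen_cfg$seed <- derive_seed(cfg$seed, 101L)
    data_dir <- file.path(cfg$out_dir %||% tempfile("ablation_data_"),
                          "data")
    ds <- generate_dataset(gen_cfg, data_dir)
    samples <- ds$samples
  }
  split <- split_train_test(samples$label,
                            train_fraction = cfg$train_fraction,
                            seed = derive_seed(cfg$seed, 202L),
                            stratified = cfg$stratified)
  prep <- preprocess_dataset(samples,
                             preprocess_config(target_size = cfg$target_size),
                             train_idx = split$train, resized = resized)
  pairs <- prep$pairs
  train_pairs <- pairs[split$train]
  test_pairs <- pairs[split$test]
  y_test <- vapply(test_pairs, function(p) p$label, integer(1L))

  reports <- list(); models <- list(); seeds <- list()
  for (arm in cfg$arms) {
    s <- arm_seed(cfg$seed, arm)
    seeds[[arm]] <- s
    if (arm == "fused_image") {
      spec <- vit_spec("tiny", image_size = cfg$target_size,
                       embed_dim = cfg$vit$embed_dim, depth = cfg$vit$depth,
                       heads = cfg$vit$heads, mlp_ratio = cfg$vit$mlp_ratio)
      model <- train_vit(train_pairs, spec,
                         vit_train_config(
                           learning_rate = cfg$vit$learning_rate,
                           weight_decay = cfg$vit$weight_decay,
                           epochs = cfg$vit$epochs,
                           batch_size = cfg$vit$batch_size,
                           warmup_steps = cfg$vit$warmup_steps %||% 0L,
                           seed = s))
      pred <- predict(model, test_pairs)
    } else {
      model <- train_feature_fusion(
        train_pairs,
        train_config(learning_rate = cfg$train$learning_rate,
                     batch_size = cfg$train$batch_size,
                     epochs = cfg$train$epochs,
                     warmup_steps = cfg$train$warmup_steps %||% 0L,
                     seed = s),
        arm = arm)
      pred <- predict_feature_fusion(model, test_pairs)
    }
    reports[[arm]] <- evaluate_predictions(y_test, pred$label, pred$score)
    models[[arm]] <- model
  }

  table <- do.call(rbind, lapply(cfg$arms, function(a) {
    r <- reports[[a]]
    data.frame(arm = a, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, auc = r$auc,
               stringsAsFactors = FALSE)
  }))

  out <- structure(list(table = table, reports = reports, models = models,
                        split = split, seeds = seeds, config = cfg,
                        data_dir = data_dir,
                        stats_thermal = prep$stats_thermal),
                   class = "ablation_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(cfg$out_dir, "comparison.csv"),
                     row.names = FALSE)
    echo <- list(seed = cfg$seed, arms = cfg$arms, seeds = seeds,
                 target_size = cfg$target_size, train = cfg$train,
                 vit = cfg$vit, train_fraction = cfg$train_fraction,
                 stratified = cfg$stratified,
                 metrics = lapply(reports, function(r)
                   r[c("accuracy", "precision", "recall", "f1", "auc")]))
    jsonlite::write_json(echo, file.path(cfg$out_dir, "ablation.json"),
                         auto_unbox = TRUE, digits = NA)
    for (arm in cfg$arms)
      write_report(reports[[arm]], cfg$out_dir, prefix = arm)
  }
  out
}

#' Replicate an ablation study over several seeds
#'
#' Generates the dataset once from `cfg$generator` (with the generator's own
#' seed — the dataset is a fixed study condition), then re-runs the full
#' ablation for every seed in `seeds`, varying only the train/test split and
#' the training randomness. Summarizes with the per-arm median of every
#' metric across replicates.
#'
#' @param cfg A [run_config()]; if `cfg$manifest` is set, that dataset is
#'   shared as-is.
#' @param seeds Integer vector of study seeds.
#' @return An `ablation_replicates` list: `replicates` (one
#'   `ablation_report` per seed), `seeds`, `median_table`.
#' @export
run_ablation_replicates <- function(cfg, seeds) {
  stopifnot(inherits(cfg, "run_config"), length(seeds) >= 1L)
  if (is.null(cfg$manifest)) {
    dir <- file.path(cfg$out_dir %||% tempfile("ablation_data_"), "data")
    ds <- generate_dataset(cfg$generator, dir)
    cfg$manifest <- ds$manifest
  }
  # decode and resize once; only split-dependent statistics differ by seed
  samples <- read_manifest(cfg$manifest, validate = FALSE)
  resized <- resize_dataset(samples,
                            preprocess_config(target_size = cfg$target_size))
  replicates <- lapply(seeds, function(s) {
    c2 <- cfg
    c2$seed <- as.integer(s)
    if (!is.null(cfg$out_dir))
      c2$out_dir <- file.path(cfg$out_dir, paste0("seed_", s))
    run_ablation(c2, resized = resized)
  })
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  median_table <- do.call(rbind, lapply(cfg$arms, function(a) {
    row <- lapply(metrics, function(m) stats::median(vapply(
      replicates, function(r) r$table[r$table$arm == a, m], numeric(1L))))
    names(row) <- metrics
    cbind(data.frame(arm = a, stringsAsFactors = FALSE),
          as.data.frame(row))
  }))
  structure(list(replicates = replicates, seeds = as.integer(seeds),
                 median_table = median_table, config = cfg),
            class = "ablation_replicates")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Ablation study (seed", x$config$seed, "-",
      length(x$split$train), "train /", length(x$split$test), "test)\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
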