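#' Modality feature-extractor architecture
#'
#' The per-modality CNN: two 3x3 convolutions (stride 1, padding 1) with
#' channels 64 then 128, each followed by ReLU and 2x2 max-pooling, then a
#' single fully connected map from the flattened 128-channel grid to a
#' 256-dimensional feature vector (ReLU-activated). For a 224x224 input the
#' pre-flatten grid is 56x56.
#'
#' @param conv_channels Two conv output channel counts.
#' @param out_dim Feature dimension.
#' @return An `extractor_spec` list.
#' @export
extractor_spec <- function(conv_channels = c(64L, 128L), out_dim = 256L) {
  if (length(conv_channels) != 2L)
    stop_input("configuration error: exactly two conv layers")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = 3L, stride = 1L, padding = 1L, pool = 2L,
                 activation = "relu", out_dim = as.integer(out_dim)),
            class = "extractor_spec")
}

#' Fusion classifier architecture
#'
#' Fully connected 512 -> 1024 -> 512 -> 2 network with ReLU after the two
#' hidden layers and dropout (p = 0.5) after the first. The input dimension
#' shrinks to 256 for unimodal and no-fusion arms.
#'
#' @param layer_dims Layer widths, input first, 2 raw class scores last.
#' @param dropout_prob Dropout probability after the first hidden layer.
#' @return A `fusion_dnn_spec` list.
#' @export
fusion_dnn_spec <- function(layer_dims = c(512L, 1024L, 512L, 2L),
                            dropout_prob = 0.5) {
  layer_dims <- as.integer(layer_dims)
  if (layer_dims[length(layer_dims)] != 2L)
    stop_input("configuration error: output dimension must be 2")
  structure(list(layer_dims = layer_dims, dropout_prob = dropout_prob),
            class = "fusion_dnn_spec")
}

#' Training configuration for the feature-fusion path
#'
#' Defaults follow the published recipe: Adam, learning rate 1e-4,
#' cross-entropy loss, batch size 32, 10 epochs. Desk-scale experiments in
#' this package use `learning_rate = 1e-3` with fewer epochs to compensate
#' for the much smaller number of optimizer steps (see the methods
#' vignette).
#'
#' @param learning_rate Adam step size (> 0; 0 is allowed and performs no
#'   update, useful for control experiments).
#' @param batch_size Mini-batch size; the last incomplete batch is kept.
#' @param epochs Number of passes over the training set (>= 1).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param warmup_steps Linear learning-rate warmup over this many optimizer
#'   steps (0 disables it). The extractor's fully connected layer has a very
#'   large fan-in, so coherent full-size steps in the first few updates can
#'   collapse its output scale when training from scratch at elevated rates;
#'   a short warmup stabilizes this.
#' @param device Only `"cpu"` is supported.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         epochs = 10L, seed = 1L, warmup_steps = 0L,
                         device = "cpu") {
  if (learning_rate < 0)
    stop_input("configuration error: learning_rate must be >= 0")
  if (epochs < 1L) stop_input("configuration error: epochs must be >= 1")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 loss = "cross_entropy", batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 warmup_steps = as.integer(warmup_steps), device = device),
            class = "train_config")
}

#' Concatenation fusion of per-modality features
#'
#' `F_fused = [F_rgb, F_thermal]`: the RGB block occupies the first half,
#' the thermal block the second, exactly. Accepts single vectors or
#' row-per-sample matrices.
#'
#' @param f_rgb,f_thermal Numeric vectors of equal length (or matrices with
#'   equally many columns and rows).
#' @return The concatenated vector (or column-bound matrix), RGB first.
#' @export
fuse_features <- function(f_rgb, f_thermal) {
  if (is.matrix(f_rgb) || is.matrix(f_thermal)) {
    if (!is.matrix(f_rgb) || !is.matrix(f_thermal) ||
        nrow(f_rgb) != nrow(f_thermal))
      stop_input("input error: feature matrices must have equal row counts")
    return(cbind(f_rgb, f_thermal))
  }
  if (length(f_rgb) != length(f_thermal))
    stop_input("input error: feature vectors must have equal length")
  c(f_rgb, f_thermal)
}

arm_names <- function() {
  c("rgb_only", "thermal_only", "no_fusion", "fused_feature", "fused_image")
}

head_input_dim <- function(arm, out_dim = 256L) {
  if (arm == "fused_feature") 2L * out_dim else out_dim
}

#' Train the feature-level fusion classifier
#'
#' Jointly optimizes the modality extractor(s) and the fully connected head
#' end-to-end against mean cross-entropy with a single Adam optimizer. Arms:
#' `"fused_feature"` (both extractors, concatenated 512-vector into the
#' 512->1024->512->2 head), `"rgb_only"` / `"thermal_only"` (one extractor
#' into a 256-input head), and `"no_fusion"` (both extractors feeding one
#' *shared* 256-input head as independent training items; at prediction time
#' the two per-modality class probabilities are averaged).
#'
#' All randomness (initialization, epoch shuffling, dropout) derives from
#' `cfg$seed`; each epoch's shuffle uses a seed derived from the epoch
#' index, and repeated runs with one seed produce identical logs.
#'
#' @param pairs List of `preprocessed_pair` objects (both classes present).
#' @param cfg A [train_config()].
#' @param arm One of `"fused_feature"`, `"rgb_only"`, `"thermal_only"`,
#'   `"no_fusion"`.
#' @param spec An [extractor_spec()].
#' @param dnn_spec A [fusion_dnn_spec()]; its input width is adapted to the
#'   arm.
#' @return A `feature_fusion_model` with the trained parameters and a
#'   per-epoch `log` data frame (`epoch,split,loss,accuracy`).
#' @export
train_feature_fusion <- function(pairs, cfg = train_config(),
                                 arm = "fused_feature",
                                 spec = extractor_spec(),
                                 dnn_spec = fusion_dnn_spec()) {
  arm <- match.arg(arm, setdiff(arm_names(), "fused_image"))
  labels <- vapply(pairs, function(p) p$label, integer(1L))
  if (length(unique(labels)) < 2L)
    stop_input("configuration error: training set must contain both classes")
  in_size <- dim(pairs[[1L]]$rgb)[2L]
  dims <- dnn_spec$layer_dims
  dims[1L] <- head_input_dim(arm, spec$out_dim)
  use_rgb <- arm %in% c("fused_feature", "rgb_only", "no_fusion")
  use_th <- arm %in% c("fused_feature", "thermal_only", "no_fusion")

  model <- NULL
  with_seed(cfg$seed, {
    params <- list()
    if (use_rgb)
      params <- c(params, prefix_params(
        init_extractor(in_size, spec$conv_channels, spec$out_dim), "rgb."))
    if (use_th)
      params <- c(params, prefix_params(
        init_extractor(in_size, spec$conv_channels, spec$out_dim), "th."))
    params <- c(params, prefix_params(init_mlp(dims), "head."))
    opt <- adam_init(params)

    n <- length(pairs)
    log_rows <- vector("list", cfg$epochs)
    reuse_rgb <- NULL; reuse_th <- NULL # recycled float-cache buffers
    for (epoch in seq_len(cfg$epochs)) {
      set.seed(derive_seed(cfg$seed, epoch))
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0; ep_correct <- 0L; ep_items <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        y <- labels[idx]
        bp <- pairs[idx]
        fr <- ft <- NULL
        if (use_rgb) {
          fr <- extractor_forward(strip_prefix(params, "rgb."),
                                  stack_chw(lapply(bp, `[[`, "rgb")),
                                  keep_cache = TRUE, reuse = reuse_rgb)
          reuse_rgb <- fr$cache
        }
        if (use_th) {
          ft <- extractor_forward(strip_prefix(params, "th."),
                                  stack_chw(lapply(bp, `[[`, "thermal")),
                                  keep_cache = TRUE, reuse = reuse_th)
          reuse_th <- ft$cache
        }
        if (arm == "fused_feature") {
          feats <- fuse_features(fr$out, ft$out)
          y_stream <- y
        } else if (arm == "rgb_only") {
          feats <- fr$out; y_stream <- y
        } else if (arm == "thermal_only") {
          feats <- ft$out; y_stream <- y
        } else { # no_fusion: mixed unimodal stream through a shared head
          feats <- rbind(fr$out, ft$out)
          y_stream <- c(y, y)
        }
        hf <- mlp_forward(strip_prefix(params, "head."), feats, dims,
                          training = TRUE, dropout_p = dnn_spec$dropout_prob)
        ce <- cross_entropy(hf$logits, y_stream)
        if (!is.finite(ce$loss))
          stop("numerical error: non-finite loss at epoch ", epoch,
               call. = FALSE)
        if (cfg$learning_rate > 0) {
          hb <- mlp_backward(strip_prefix(params, "head."), hf$cache, dims,
                             ce$grad, dnn_spec$dropout_prob)
          opt$t <- opt$t + 1L
          lr_t <- cfg$learning_rate *
            if (cfg$warmup_steps > 0) min(1, opt$t / cfg$warmup_steps) else 1
          # head update (tiny tensors): fused in-place Adam per parameter
          for (nm in names(hb$grads))
            .adam_update_inplace(params[[paste0("head.", nm)]],
                                 hb$grads[[nm]],
                                 opt$m[[paste0("head.", nm)]],
                                 opt$v[[paste0("head.", nm)]],
                                 opt$t, lr_t,
                                 0.9, 0.999, 1e-8, 0)
          # extractor updates: backward fused with Adam in C++
          ext_upd <- function(prefix, cache, dx) {
            .ext_backward_adam_f(cache, strip_prefix(params, prefix), dx,
                                 strip_prefix(opt$m, prefix),
                                 strip_prefix(opt$v, prefix),
                                 opt$t, lr_t,
                                 0.9, 0.999, 1e-8)
          }
          od <- spec$out_dim
          if (arm == "fused_feature") {
            ext_upd("rgb.", fr$cache, hb$dx[, seq_len(od), drop = FALSE])
            ext_upd("th.", ft$cache,
                    hb$dx[, od + seq_len(od), drop = FALSE])
          } else if (arm == "rgb_only") {
            ext_upd("rgb.", fr$cache, hb$dx)
          } else if (arm == "thermal_only") {
            ext_upd("th.", ft$cache, hb$dx)
          } else {
            nb <- length(idx)
            ext_upd("rgb.", fr$cache, hb$dx[seq_len(nb), , drop = FALSE])
            ext_upd("th.", ft$cache,
                    hb$dx[nb + seq_len(nb), , drop = FALSE])
          }
          rm(hb)
        }
        ep_loss <- ep_loss + ce$loss * length(y_stream)
        ep_correct <- ep_correct +
          sum(argmax_label(hf$logits) == y_stream)
        ep_items <- ep_items + length(y_stream)
        rm(fr, ft, hf)
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, split = "train",
        loss = ep_loss / ep_items,
        accuracy = ep_correct / ep_items)
    }
    model <- structure(list(
      arm = arm, params = params, head_dims = dims, input_size = in_size,
      spec = spec, dnn_spec = dnn_spec, train_config = cfg,
      log = do.call(rbind, log_rows)), class = "feature_fusion_model")
  })
  model
}

# Evaluation-mode features for a batch of pairs, per modality.
model_features <- function(model, pairs, modality, batch_size = 64L) {
  prefix <- if (modality == "rgb") "rgb." else "th."
  field <- if (modality == "rgb") "rgb" else "thermal"
  p <- strip_prefix(model$params, prefix)
  if (!length(p))
    stop_input("input error: model has no ", modality, " extractor")
  n <- length(pairs)
  out <- matrix(0, n, model$spec$out_dim)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    x <- stack_chw(lapply(pairs[idx], `[[`, field))
    out[idx, ] <- extractor_forward(p, x)$out
  }
  out
}

#' Extract 256-dimensional feature vectors
#'
#' Evaluation-mode (deterministic) forward pass through the requested
#' modality extractor.
#'
#' @param model A trained `feature_fusion_model`.
#' @param pair A `preprocessed_pair`, a `(3, s, s)` array matching the
#'   model's input size, or a list of `preprocessed_pair`s (batched).
#' @param modality `"rgb"` or `"thermal"`.
#' @return Numeric vector of length `model$spec$out_dim` (256), or an
#'   `n x 256` matrix for a list input.
#' @export
extract_features <- function(model, pair, modality = c("rgb", "thermal")) {
  modality <- match.arg(modality)
  if (is.list(pair) && !inherits(pair, "preprocessed_pair"))
    return(model_features(model, pair, modality))
  x <- if (inherits(pair, "preprocessed_pair"))
    pair[[if (modality == "rgb") "rgb" else "thermal"]] else pair
  d <- dim(x)
  if (length(d) != 3L || d[1L] != 3L || d[2L] != model$input_size ||
      d[3L] != model$input_size)
    stop_input("input error: expected a (3, ", model$input_size, ", ",
               model$input_size, ") array")
  p <- strip_prefix(model$params,
                    if (modality == "rgb") "rgb." else "th.")
  if (!length(p))
    stop_input("input error: model has no ", modality, " extractor")
  as.numeric(extractor_forward(p, array(x, c(d, 1L)))$out)
}

#' Classify a fused feature vector
#'
#' Evaluation-mode pass of a fused (or unimodal, depending on the model's
#' arm) feature vector through the fully connected head. The predicted label
#' is the argmax of the two raw scores; exact ties resolve to the lower
#' index (class 0, FAW).
#'
#' @param model A trained `feature_fusion_model`.
#' @param f_fused Numeric vector whose length matches the head input (512
#'   for the fused arm), or a row-per-sample matrix.
#' @return List with `scores` (raw 2-column score matrix), `prob` (softmax),
#'   and `label` (0/1 integer vector).
#' @export
classify_fused <- function(model, f_fused) {
  if (!is.matrix(f_fused)) f_fused <- matrix(f_fused, nrow = 1L)
  if (ncol(f_fused) != model$head_dims[1L])
    stop_input("input error: expected feature dimension ",
               model$head_dims[1L])
  hf <- mlp_forward(strip_prefix(model$params, "head."), f_fused,
                    model$head_dims, training = FALSE)
  list(scores = hf$logits, prob = softmax(hf$logits),
       label = argmax_label(hf$logits))
}

#' Predict labels and class probabilities for preprocessed pairs
#'
#' @param model A trained `feature_fusion_model`.
#' @param pairs List of `preprocessed_pair` objects.
#' @param batch_size Evaluation batch size.
#' @return List with `logits`, `prob` (n x 2), `label` (0/1), and `score` —
#'   the probability of the positive class FAW (label 0), used for ROC/PR
#'   curves. For the no-fusion arm, `prob` is the mean of the two unimodal
#'   softmax outputs and `logits` is `NA`.
#' @export
predict_feature_fusion <- function(model, pairs, batch_size = 64L) {
  arm <- model$arm
  if (arm == "no_fusion") {
    pr <- classify_fused(model, model_features(model, pairs, "rgb",
                                               batch_size))$prob
    pt <- classify_fused(model, model_features(model, pairs, "thermal",
                                               batch_size))$prob
    prob <- (pr + pt) / 2
    return(list(logits = NA, prob = prob,
                label = argmax_label(prob), score = prob[, 1L]))
  }
  feats <- switch(arm,
    fused_feature = fuse_features(
      model_features(model, pairs, "rgb", batch_size),
      model_features(model, pairs, "thermal", batch_size)),
    rgb_only = model_features(model, pairs, "rgb", batch_size),
    thermal_only = model_features(model, pairs, "thermal", batch_size))
  cf <- classify_fused(model, feats)
  list(logits = cf$scores, prob = cf$prob, label = cf$label,
       score = cf$prob[, 1L])
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the weights, the architecture and training
#' configuration echo, and the package version string.
#'
#' @param model A `feature_fusion_model` or `vit_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(model = model,
               package_version = as.character(utils::packageVersion("fawfusion"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_input("missing checkpoint: ", path)
  readRDS(path)$model
}
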