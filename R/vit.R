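#' Stack a preprocessed pair into a 6-channel fused image
#'
#' `I_fused = [I_RGB, I_thermal]`: channels 0-2 are the normalized RGB
#' array, channels 3-5 the normalized thermal array. Lossless —
#' [unfuse_images()] recovers both inputs bit-exactly by slicing.
#'
#' @param pair A `preprocessed_pair`, or a list with `(3, H, W)` arrays
#'   `rgb` and `thermal` of identical shape.
#' @return A `(6, H, W)` array.
#' @export
fuse_images <- function(pair) {
  rgb <- pair$rgb; th <- pair$thermal
  dr <- dim(rgb); dt <- dim(th)
  if (length(dr) != 3L || length(dt) != 3L || dr[1L] != 3L ||
      dt[1L] != 3L || !identical(dr[2:3], dt[2:3]))
    stop_input("input error: rgb and thermal must both be (3, H, W) arrays ",
               "of identical spatial size")
  out <- array(0, c(6L, dr[2L], dr[3L]))
  out[1:3, , ] <- rgb
  out[4:6, , ] <- th
  out
}

#' Recover the RGB and thermal halves of a fused image
#' @param i_fused A `(6, H, W)` array from [fuse_images()].
#' @return List with `(3, H, W)` arrays `rgb` and `thermal`.
#' @export
unfuse_images <- function(i_fused) {
  d <- dim(i_fused)
  if (length(d) != 3L || d[1L] != 6L)
    stop_input("input error: expected a (6, H, W) array")
  list(rgb = i_fused[1:3, , , drop = FALSE] |> array(c(3L, d[2L], d[3L])),
       thermal = i_fused[4:6, , , drop = FALSE] |> array(c(3L, d[2L], d[3L])))
}

#' Vision-transformer architecture for 6-channel fused images
#'
#' The patch embedding is a 16x16, stride-16 convolution widened to 6 input
#' channels (equivalently, a linear map of each flattened 6x16x16 patch);
#' a learned class token plus learned positional embeddings feed a standard
#' pre-norm transformer encoder with a linear classification head on the
#' class token. The `"paper"` profile matches ViT-Base; the `"tiny"` profile
#' is a small configuration for desk-scale experiments, trainable from
#' scratch in minutes on one CPU.
#'
#' @param profile `"tiny"` (embed 64, depth 2, 4 heads, mlp ratio 2, image
#'   96) or `"paper"` (embed 768, depth 12, 12 heads, mlp ratio 4, image
#'   224). Individual fields can be overridden.
#' @param image_size,embed_dim,depth,heads,mlp_ratio Architecture overrides.
#' @param patch_size Patch side (16).
#' @param init_mode `"scratch"` (default) or `"inflate_pretrained"` — the
#'   latter requires 3-channel pretrained patch weights at build time; see
#'   [inflate_patch_weights()].
#' @return A `vit_spec` list; `image_size` must be divisible by
#'   `patch_size`, giving `(image_size / patch_size)^2` tokens.
#' @export
vit_spec <- function(profile = c("tiny", "paper"), image_size = NULL,
                     embed_dim = NULL, depth = NULL, heads = NULL,
                     mlp_ratio = NULL, patch_size = 16L,
                     init_mode = c("scratch", "inflate_pretrained")) {
  profile <- match.arg(profile)
  def <- if (profile == "tiny")
    list(image_size = 96L, embed_dim = 64L, depth = 2L, heads = 4L,
         mlp_ratio = 2L)
  else
    list(image_size = 224L, embed_dim = 768L, depth = 12L, heads = 12L,
         mlp_ratio = 4L)
  s <- list(in_channels = 6L, patch_size = as.integer(patch_size),
            image_size = as.integer(image_size %||% def$image_size),
            embed_dim = as.integer(embed_dim %||% def$embed_dim),
            depth = as.integer(depth %||% def$depth),
            heads = as.integer(heads %||% def$heads),
            mlp_ratio = as.integer(mlp_ratio %||% def$mlp_ratio),
            num_classes = 2L, profile = profile,
            init_mode = match.arg(init_mode))
  if (s$image_size %% s$patch_size != 0L)
    stop_input("configuration error: image_size must be divisible by ",
               "patch_size")
  if (s$embed_dim %% s$heads != 0L)
    stop_input("configuration error: embed_dim must be divisible by heads")
  structure(s, class = "vit_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training configuration for the image-fusion ViT
#'
#' AdamW (decoupled weight decay on weight matrices only) minimizing
#' two-class cross-entropy on softmax outputs — algebraically identical to
#' the binary form `-(y log yhat + (1-y) log(1-yhat))` with `yhat` the
#' probability of class 1.
#'
#' @param learning_rate AdamW step size (default 1e-4, the fine-tuning
#'   rate; from-scratch tiny-profile training uses 1e-3).
#' @param weight_decay Decoupled weight decay coefficient.
#' @param epochs,batch_size,seed As in [train_config()].
#' @param warmup_steps Linear learning-rate warmup over this many optimizer
#'   steps (standard for transformer training; 0 disables it).
#' @return A `vit_train_config` list.
#' @export
vit_train_config <- function(learning_rate = 1e-4, weight_decay = 0.01,
                             epochs = 10L, batch_size = 16L, seed = 1L,
                             warmup_steps = 0L) {
  if (learning_rate < 0)
    stop_input("configuration error: learning_rate must be >= 0")
  if (epochs < 1L) stop_input("configuration error: epochs must be >= 1")
  structure(list(optimizer = "adamw", learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 warmup_steps = as.integer(warmup_steps),
                 loss = "cross_entropy"),
            class = "vit_train_config")
}

# Linear index table mapping (patch element p, token t) into a (C, H, W)
# array; patch elements are channel-fastest, tokens row-major over the grid.
patch_index <- function(spec, H, W) {
  ps <- spec$patch_size; C <- spec$in_channels
  g_h <- H %/% ps; g_w <- W %/% ps
  P <- C * ps * ps
  # offsets within one patch (0-based): c + C*i + C*H*j
  kc <- rep(0:(C - 1L), times = ps * ps)
  ki <- rep(rep(0:(ps - 1L), each = C), times = ps)
  kj <- rep(0:(ps - 1L), each = C * ps)
  off <- kc + C * ki + C * H * kj
  # token origins, row-major over (gi, gj): token index t = gj + g_w*gi
  gi <- rep(0:(g_h - 1L), each = g_w)
  gj <- rep(0:(g_w - 1L), times = g_h)
  orig <- C * (gi * ps) + C * H * (gj * ps)
  matrix(rep(off, times = length(orig)) +
           rep(orig, each = P), P, g_h * g_w) + 1L
}

# Patch matrix (T x P) for one fused image.
extract_patches <- function(i_fused, spec) {
  d <- dim(i_fused)
  if (length(d) != 3L || d[1L] != spec$in_channels)
    stop_input("input error: expected a (", spec$in_channels, ", H, W) array")
  if (d[2L] %% spec$patch_size != 0L || d[3L] %% spec$patch_size != 0L)
    stop_input("configuration error: spatial dims must be divisible by ",
               "patch_size")
  idx <- patch_index(spec, d[2L], d[3L])
  t(matrix(i_fused[idx], nrow(idx), ncol(idx)))
}

#' Initialize a ViT model
#'
#' Fan-in uniform initialization for all linear maps, zeros for the class
#' token, N(0, 0.02) positional embeddings, unit layer-norm gains.
#' Randomness comes from the caller's RNG stream (wrap in a seeded context
#' for reproducibility); [train_vit()] seeds it from its config.
#'
#' @param spec A [vit_spec()].
#' @param pretrained_patch_w Optional 3-channel patch-embedding weight
#'   matrix `(3 * patch_size^2) x embed_dim` used when
#'   `spec$init_mode == "inflate_pretrained"`.
#' @return A `vit_model` list (untrained).
#' @export
init_vit <- function(spec, pretrained_patch_w = NULL) {
  D <- spec$embed_dim
  P <- spec$in_channels * spec$patch_size^2
  Tn <- (spec$image_size %/% spec$patch_size)^2
  p <- list(patch_w = init_uniform(P, D, P), patch_b = init_bias(D, P),
            cls = matrix(0, 1L, D),
            pos = matrix(rnorm((Tn + 1L) * D, 0, 0.02), Tn + 1L, D))
  if (spec$init_mode == "inflate_pretrained") {
    if (is.null(pretrained_patch_w))
      stop_input("configuration error: inflate_pretrained requires ",
                 "pretrained_patch_w")
    p$patch_w <- inflate_patch_weights(pretrained_patch_w, spec$patch_size)
  }
  for (l in seq_len(spec$depth)) {
    pre <- paste0("b", l, "_")
    p[[paste0(pre, "ln1_g")]] <- rep(1, D)
    p[[paste0(pre, "ln1_o")]] <- rep(0, D)
    p[[paste0(pre, "qkv_w")]] <- init_uniform(D, 3L * D, D)
    p[[paste0(pre, "qkv_b")]] <- init_bias(3L * D, D)
    p[[paste0(pre, "proj_w")]] <- init_uniform(D, D, D)
    p[[paste0(pre, "proj_b")]] <- init_bias(D, D)
    p[[paste0(pre, "ln2_g")]] <- rep(1, D)
    p[[paste0(pre, "ln2_o")]] <- rep(0, D)
    dm <- D * spec$mlp_ratio
    p[[paste0(pre, "mlp1_w")]] <- init_uniform(D, dm, D)
    p[[paste0(pre, "mlp1_b")]] <- init_bias(dm, D)
    p[[paste0(pre, "mlp2_w")]] <- init_uniform(dm, D, dm)
    p[[paste0(pre, "mlp2_b")]] <- init_bias(D, dm)
  }
  p$lnf_g <- rep(1, D); p$lnf_o <- rep(0, D)
  # zero-initialized head: initial logits are exactly 0 for both classes,
  # avoiding a random class tilt that short training runs calibrate slowly
  p$head_w <- matrix(0, D, spec$num_classes)
  p$head_b <- rep(0, spec$num_classes)
  structure(list(spec = spec, params = p, log = NULL), class = "vit_model")
}

#' Adapt 3-channel patch-embedding weights to 6 channels
#'
#' Duplicates each RGB kernel element onto the corresponding thermal
#' channel and halves all weights, so an input whose RGB and thermal blocks
#' both equal the original 3-channel image produces exactly the original
#' pre-activation embedding.
#'
#' @param w3 Matrix `(3 * patch_size^2) x embed_dim`, channel-fastest rows.
#' @param patch_size Patch side.
#' @return Matrix `(6 * patch_size^2) x embed_dim`.
#' @export
inflate_patch_weights <- function(w3, patch_size) {
  px <- patch_size^2
  if (nrow(w3) != 3L * px)
    stop_input("input error: w3 must have 3 * patch_size^2 rows")
  w6 <- matrix(0, 6L * px, ncol(w3))
  pix <- rep(0:(px - 1L), each = 6L)
  c6 <- rep(0:5L, times = px)
  c3 <- c6 %% 3L
  w6[c6 + 6L * pix + 1L, ] <- w3[c3 + 3L * pix + 1L, ] / 2
  w6
}

#' Patch-embed a fused image
#'
#' Applies the model's strided 6-channel convolutional patch embedding,
#' returning one `embed_dim`-vector per 16x16 patch —
#' `(H / patch_size) * (W / patch_size)` tokens in row-major grid order.
#'
#' @param model A `vit_model` (or anything with `spec` and `params`).
#' @param i_fused `(6, H, W)` array with spatial dims divisible by the patch
#'   size.
#' @return Matrix `(tokens x embed_dim)`.
#' @export
patch_embed <- function(model, i_fused) {
  xp <- extract_patches(i_fused, model$spec)
  sweep(xp %*% model$params$patch_w, 2L, model$params$patch_b, "+")
}

layernorm_forward <- function(x, g, o, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(out = sweep(sweep(xhat, 2L, g, "*"), 2L, o, "+"), # y = xhat*g + o
       xhat = xhat, istd = istd)
}

layernorm_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, "*")
  dg <- colSums(dy * cache$xhat)
  do_ <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$istd * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = dg, do_ = do_)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Full transformer forward on a list of fused images; returns logits and,
# when keep_cache, everything backward needs.
vit_forward <- function(model, fused_list, keep_cache = FALSE) {
  spec <- model$spec; p <- model$params
  N <- length(fused_list)
  D <- spec$embed_dim; nh <- spec$heads; dh <- D %/% nh
  xp <- do.call(rbind, lapply(fused_list, extract_patches, spec = spec))
  Tn <- nrow(xp) %/% N
  if (Tn + 1L != nrow(p$pos))
    stop_input("configuration error: token count ", Tn,
               " does not match positional embeddings (", nrow(p$pos) - 1L,
               " patches)")
  emb <- sweep(xp %*% p$patch_w, 2L, p$patch_b, "+")
  Tp1 <- Tn + 1L
  h <- matrix(0, N * Tp1, D)
  cls_rows <- (seq_len(N) - 1L) * Tp1 + 1L
  for (n in seq_len(N)) {
    h[(n - 1L) * Tp1 + 1L, ] <- p$cls
    h[(n - 1L) * Tp1 + 1L + seq_len(Tn), ] <- emb[(n - 1L) * Tn + seq_len(Tn), ]
  }
  h <- h + p$pos[rep(seq_len(Tp1), N), ]
  blocks <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    pre <- paste0("b", l, "_")
    cb <- list(h_in = h)
    ln1 <- layernorm_forward(h, p[[paste0(pre, "ln1_g")]],
                             p[[paste0(pre, "ln1_o")]])
    cb$ln1 <- ln1
    qkv <- sweep(ln1$out %*% p[[paste0(pre, "qkv_w")]], 2L,
                 p[[paste0(pre, "qkv_b")]], "+")
    cb$qkv <- qkv
    attn <- matrix(0, N * Tp1, D)
    A_all <- array(0, c(Tp1, Tp1, nh, N))
    for (n in seq_len(N)) {
      rows <- (n - 1L) * Tp1 + seq_len(Tp1)
      for (hd in seq_len(nh)) {
        cq <- (hd - 1L) * dh + seq_len(dh)
        Q <- qkv[rows, cq, drop = FALSE]
        K <- qkv[rows, D + cq, drop = FALSE]
        V <- qkv[rows, 2L * D + cq, drop = FALSE]
        S <- tcrossprod(Q, K) / sqrt(dh)
        A <- exp(S - apply(S, 1L, max))
        A <- A / rowSums(A)
        A_all[, , hd, n] <- A
        attn[rows, cq] <- A %*% V
      }
    }
    cb$A <- A_all; cb$attn_cat <- attn
    proj <- sweep(attn %*% p[[paste0(pre, "proj_w")]], 2L,
                  p[[paste0(pre, "proj_b")]], "+")
    h <- h + proj
    cb$h_mid <- h
    ln2 <- layernorm_forward(h, p[[paste0(pre, "ln2_g")]],
                             p[[paste0(pre, "ln2_o")]])
    cb$ln2 <- ln2
    z1 <- sweep(ln2$out %*% p[[paste0(pre, "mlp1_w")]], 2L,
                p[[paste0(pre, "mlp1_b")]], "+")
    cb$z1 <- z1
    a1 <- gelu(z1)
    cb$a1 <- a1
    m2 <- sweep(a1 %*% p[[paste0(pre, "mlp2_w")]], 2L,
                p[[paste0(pre, "mlp2_b")]], "+")
    h <- h + m2
    blocks[[l]] <- if (keep_cache) cb else NULL
  }
  lnf <- layernorm_forward(h, p$lnf_g, p$lnf_o)
  cls_out <- lnf$out[cls_rows, , drop = FALSE]
  logits <- sweep(cls_out %*% p$head_w, 2L, p$head_b, "+")
  cache <- NULL
  if (keep_cache)
    cache <- list(xp = xp, blocks = blocks, lnf = lnf, h_last = h,
                  cls_rows = cls_rows, cls_out = cls_out, N = N, Tp1 = Tp1)
  list(logits = logits, cache = cache)
}

vit_backward <- function(model, cache, dlogits) {
  spec <- model$spec; p <- model$params
  D <- spec$embed_dim; nh <- spec$heads; dh <- D %/% nh
  N <- cache$N; Tp1 <- cache$Tp1; Tn <- Tp1 - 1L
  g <- list(head_w = crossprod(cache$cls_out, dlogits),
            head_b = colSums(dlogits))
  dln_out <- matrix(0, N * Tp1, D)
  dln_out[cache$cls_rows, ] <- tcrossprod(dlogits, p$head_w)
  lb <- layernorm_backward(dln_out, cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_o <- lb$do_
  dh_ <- lb$dx
  for (l in rev(seq_len(spec$depth))) {
    pre <- paste0("b", l, "_")
    cb <- cache$blocks[[l]]
    # MLP branch
    dm2 <- dh_
    g[[paste0(pre, "mlp2_w")]] <- crossprod(cb$a1, dm2)
    g[[paste0(pre, "mlp2_b")]] <- colSums(dm2)
    da1 <- tcrossprod(dm2, p[[paste0(pre, "mlp2_w")]])
    dz1 <- da1 * gelu_grad(cb$z1)
    g[[paste0(pre, "mlp1_w")]] <- crossprod(cb$ln2$out, dz1)
    g[[paste0(pre, "mlp1_b")]] <- colSums(dz1)
    dln2_out <- tcrossprod(dz1, p[[paste0(pre, "mlp1_w")]])
    lb2 <- layernorm_backward(dln2_out, cb$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_o")]] <- lb2$do_
    dh_ <- dh_ + lb2$dx # residual
    # attention branch
    dproj <- dh_
    g[[paste0(pre, "proj_w")]] <- crossprod(cb$attn_cat, dproj)
    g[[paste0(pre, "proj_b")]] <- colSums(dproj)
    dattn <- tcrossprod(dproj, p[[paste0(pre, "proj_w")]])
    dqkv <- matrix(0, N * Tp1, 3L * D)
    for (n in seq_len(N)) {
      rows <- (n - 1L) * Tp1 + seq_len(Tp1)
      for (hd in seq_len(nh)) {
        cq <- (hd - 1L) * dh + seq_len(dh)
        Q <- cb$qkv[rows, cq, drop = FALSE]
        K <- cb$qkv[rows, D + cq, drop = FALSE]
        V <- cb$qkv[rows, 2L * D + cq, drop = FALSE]
        A <- cb$A[, , hd, n]
        dO <- dattn[rows, cq, drop = FALSE]
        dV <- crossprod(A, dO)
        dA <- tcrossprod(dO, V)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dqkv[rows, cq] <- dS %*% K
        dqkv[rows, D + cq] <- crossprod(dS, Q)
        dqkv[rows, 2L * D + cq] <- dV
      }
    }
    g[[paste0(pre, "qkv_w")]] <- crossprod(cb$ln1$out, dqkv)
    g[[paste0(pre, "qkv_b")]] <- colSums(dqkv)
    dln1_out <- tcrossprod(dqkv, p[[paste0(pre, "qkv_w")]])
    lb1 <- layernorm_backward(dln1_out, cb$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_o")]] <- lb1$do_
    dh_ <- dh_ + lb1$dx # residual into block input
  }
  # token assembly: h0 = [cls; emb] + pos
  g$pos <- unname(rowsum(dh_, rep(seq_len(Tp1), N))) # rows ordered 1..Tp1
  g$cls <- matrix(colSums(dh_[cache$cls_rows, , drop = FALSE]), 1L, D)
  demb <- dh_[-cache$cls_rows, , drop = FALSE]
  g$patch_w <- crossprod(cache$xp, demb)
  g$patch_b <- colSums(demb)
  g
}

#' Train the 6-channel image-fusion ViT
#'
#' Minimizes two-class cross-entropy on the fused 6-channel inputs with
#' AdamW, all randomness seeded from `cfg$seed` (identical seed, identical
#' loss log).
#'
#' @param pairs List of `preprocessed_pair` objects; both classes required.
#' @param spec A [vit_spec()].
#' @param cfg A [vit_train_config()].
#' @param pretrained_patch_w Passed to [init_vit()] when inflating.
#' @return A trained `vit_model` with a per-epoch `log` data frame.
#' @export
train_vit <- function(pairs, spec = vit_spec("tiny"),
                      cfg = vit_train_config(),
                      pretrained_patch_w = NULL) {
  labels <- vapply(pairs, function(p) p$label, integer(1L))
  if (length(unique(labels)) < 2L)
    stop_input("configuration error: training set must contain both classes")
  fused <- lapply(pairs, fuse_images)
  model <- NULL
  with_seed(cfg$seed, {
    model <- init_vit(spec, pretrained_patch_w)
    opt <- adam_init(model$params)
    n <- length(fused)
    log_rows <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      set.seed(derive_seed(cfg$seed, epoch))
      perm <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L; ep_items <- 0L
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        fw <- vit_forward(model, fused[idx], keep_cache = TRUE)
        ce <- cross_entropy(fw$logits, labels[idx])
        if (!is.finite(ce$loss))
          stop("numerical error: non-finite loss at epoch ", epoch,
               call. = FALSE)
        if (cfg$learning_rate > 0) {
          grads <- vit_backward(model, fw$cache, ce$grad)
          lr_t <- cfg$learning_rate *
            if (cfg$warmup_steps > 0) min(1, (opt$t + 1L) / cfg$warmup_steps)
            else 1
          st <- adam_step(model$params, grads, opt, lr_t,
                          weight_decay = cfg$weight_decay)
          model$params <- st$params; opt <- st$state
        }
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_correct <- ep_correct + sum(argmax_label(fw$logits) == labels[idx])
        ep_items <- ep_items + length(idx)
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, split = "train",
                                      loss = ep_loss / ep_items,
                                      accuracy = ep_correct / ep_items)
    }
    model$log <- do.call(rbind, log_rows)
    model$train_config <- cfg
  })
  model
}

#' Predict from fused images with a ViT model
#'
#' Softmax probabilities sum to 1 within 1e-6; the predicted label is the
#' argmax of the logits with lowest-index tie-break (0 = FAW).
#'
#' @param object A `vit_model`.
#' @param i_fused A single `(6, H, W)` array, a list of them, or a list of
#'   `preprocessed_pair` objects (fused on the fly).
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return List with `logits`, `prob` (`class_probabilities`), `label`
#'   (`pred_label`), and `score` — the FAW-class probability.
#' @export
predict.vit_model <- function(object, i_fused, batch_size = 32L, ...) {
  if (is.array(i_fused)) i_fused <- list(i_fused)
  if (inherits(i_fused[[1L]], "preprocessed_pair"))
    i_fused <- lapply(i_fused, fuse_images)
  n <- length(i_fused)
  logits <- matrix(0, n, 2L)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    logits[idx, ] <- vit_forward(object, i_fused[idx])$logits
  }
  prob <- softmax(logits)
  list(logits = logits, prob = prob, label = argmax_label(logits),
       score = prob[, 1L])
}

#' @export
predict.feature_fusion_model <- function(object, pairs, ...) {
  predict_feature_fusion(object, pairs, ...)
}
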