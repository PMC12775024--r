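ns <- asNamespace("fawfusion")

test_that("fuse/unfuse is a bit-exact round trip with RGB channels first", {
  withr::with_seed(1L, {
    rgb <- array(rnorm(3 * 32 * 32), c(3L, 32L, 32L))
    th <- array(rnorm(3 * 32 * 32), c(3L, 32L, 32L))
  })
  fused <- fuse_images(list(rgb = rgb, thermal = th))
  expect_equal(dim(fused), c(6L, 32L, 32L))
  expect_identical(fused[1:3, , ] |> array(dim(rgb)), rgb)
  back <- unfuse_images(fused)
  expect_identical(back$rgb, rgb)
  expect_identical(back$thermal, th)
  # distinct pairs give distinct arrays
  fused2 <- fuse_images(list(rgb = th, thermal = rgb))
  expect_false(identical(fused, fused2))
  expect_error(fuse_images(list(rgb = rgb, thermal = th[, 1:16, ])),
               "identical spatial")
  expect_error(unfuse_images(rgb), "6, H, W")
})

test_that("token count follows (image_size / patch_size)^2", {
  # 224 -> 196 tokens; 96 -> 36; 32 -> 4
  for (case in list(c(224L, 196L), c(96L, 36L), c(32L, 4L))) {
    spec <- vit_spec("tiny", image_size = case[1L], embed_dim = 16L,
                     depth = 1L, heads = 2L)
    m <- withr::with_seed(1L, init_vit(spec))
    emb <- patch_embed(m, array(0, c(6L, case[1L], case[1L])))
    expect_equal(nrow(emb), case[2L])
    expect_equal(ncol(emb), 16L)
  }
  expect_error(vit_spec("tiny", image_size = 100L), "divisible")
  # zero input with zero bias embeds to all-zero tokens (linearity)
  spec <- vit_spec("tiny", image_size = 32L, embed_dim = 16L, depth = 1L,
                   heads = 2L)
  m <- withr::with_seed(1L, init_vit(spec))
  m$params$patch_b[] <- 0
  expect_equal(max(abs(patch_embed(m, array(0, c(6L, 32L, 32L))))), 0)
})

test_that("softmax predictions normalize and tie-break to class 0", {
  expect_equal(ns$softmax(matrix(c(log(3), 0), 1L)),
               matrix(c(0.75, 0.25), 1L), tolerance = 1e-12)
  expect_equal(ns$softmax(matrix(c(0, 0), 1L)), matrix(c(0.5, 0.5), 1L))
  expect_equal(ns$argmax_label(matrix(c(0, 0), 1L)), 0L)
  withr::with_seed(3L, logits <- matrix(rnorm(200), 100L, 2L))
  p <- ns$softmax(logits)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(ns$argmax_label(logits) %in% c(0L, 1L)))
})

test_that("transformer forward is batch-independent and backward matches finite differences", {
  spec <- vit_spec("tiny", image_size = 32L, embed_dim = 8L, depth = 2L,
                   heads = 2L, mlp_ratio = 2L)
  model <- withr::with_seed(3L, init_vit(spec))
  withr::with_seed(4L, {
    fused <- lapply(1:3, function(i) array(rnorm(6 * 32 * 32),
                                           c(6L, 32L, 32L)))
  })
  y <- c(0L, 1L, 0L)
  l_all <- ns$vit_forward(model, fused)$logits
  l_one <- t(vapply(fused, function(f)
    as.numeric(ns$vit_forward(model, list(f))$logits), numeric(2L)))
  expect_equal(l_all, l_one, tolerance = 1e-12)

  fw <- ns$vit_forward(model, fused, keep_cache = TRUE)
  ce <- ns$cross_entropy(fw$logits, y)
  gr <- ns$vit_backward(model, fw$cache, ce$grad)
  vloss <- function(pp) {
    m2 <- model; m2$params <- pp
    ns$cross_entropy(ns$vit_forward(m2, fused)$logits, y)$loss
  }
  # spot-check a representative subset of parameter tensors
  for (nm in c("patch_w", "pos", "cls", "b1_qkv_w", "b1_ln1_g",
               "b2_mlp1_w", "b2_proj_b", "lnf_g", "head_w")) {
    z <- as.numeric(model$params[[nm]])
    pick <- if (length(z) > 60L)
      withr::with_seed(7L, sample.int(length(z), 60L)) else seq_along(z)
    num <- vapply(pick, function(i) {
      zp <- z; zp[i] <- zp[i] + 1e-5
      zm <- z; zm[i] <- zm[i] - 1e-5
      pp <- model$params
      pp[[nm]][] <- zp; up <- vloss(pp)
      pp[[nm]][] <- zm; dn <- vloss(pp)
      (up - dn) / 2e-5
    }, numeric(1L))
    expect_equal(as.numeric(gr[[nm]])[pick], num, tolerance = 1e-5,
                 label = paste("grad", nm))
  }
})

test_that("ViT training is seeded-deterministic and zero-lr is a no-op", {
  pairs <- separable_pairs(n = 8L, size = 32L)
  spec <- vit_spec("tiny", image_size = 32L, embed_dim = 16L, depth = 1L,
                   heads = 2L)
  cfg <- vit_train_config(learning_rate = 1e-3, epochs = 3L,
                          batch_size = 4L, seed = 6L)
  m1 <- train_vit(pairs, spec, cfg)
  m2 <- train_vit(pairs, spec, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  # zero learning rate: parameters equal the seeded initialization
  cfg0 <- vit_train_config(learning_rate = 0, epochs = 2L, batch_size = 4L,
                           seed = 6L)
  m0 <- train_vit(pairs, spec, cfg0)
  ref <- withr::with_seed(6L, init_vit(spec))
  expect_equal(m0$params, ref$params)
  expect_error(train_vit(pairs[1:4], spec, cfg), "both classes")
})

test_that("predictions expose logits, probabilities and labels coherently", {
  pairs <- separable_pairs(n = 8L, size = 32L)
  spec <- vit_spec("tiny", image_size = 32L, embed_dim = 16L, depth = 1L,
                   heads = 2L)
  m <- train_vit(pairs, spec,
                 vit_train_config(learning_rate = 1e-3, epochs = 2L,
                                  batch_size = 4L, seed = 6L))
  pred <- predict(m, pairs)
  expect_equal(dim(pred$logits), c(8L, 2L))
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
  expect_identical(pred$label, ns$argmax_label(pred$logits))
  expect_equal(pred$score, pred$prob[, 1L])
  # single fused array input
  one <- predict(m, fuse_images(pairs[[1L]]))
  expect_equal(dim(one$logits), c(1L, 2L))
})

test_that("inflating 3-channel patch weights preserves duplicated-input embeddings", {
  ps <- 16L; D <- 8L
  withr::with_seed(2L, {
    w3 <- matrix(rnorm(3L * ps^2 * D), 3L * ps^2, D)
    img3 <- array(runif(3L * 32L * 32L), c(3L, 32L, 32L))
  })
  w6 <- inflate_patch_weights(w3, ps)
  expect_equal(dim(w6), c(6L * ps^2, D))
  spec3 <- list(in_channels = 3L, patch_size = ps)
  spec6 <- vit_spec("tiny", image_size = 32L, embed_dim = D, depth = 1L,
                    heads = 2L)
  p3 <- ns$extract_patches(img3, structure(spec3, class = "vit_spec"))
  fused <- fuse_images(list(rgb = img3, thermal = img3))
  p6 <- ns$extract_patches(fused, spec6)
  expect_equal(p6 %*% w6, p3 %*% w3, tolerance = 1e-12)
})
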