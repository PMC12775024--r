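test_that("manifest read validates rows and round-trips losslessly", {
  ds <- small_dataset()
  m1 <- read_manifest(ds$manifest)
  expect_equal(nrow(m1), 12L)
  expect_identical(m1$pair_id, ds$samples$pair_id)
  expect_identical(m1$label, ds$samples$label)
  # round trip
  out <- tempfile(fileext = ".csv")
  write_manifest(m1, out)
  m2 <- read_manifest(out, validate = FALSE)
  expect_identical(m2[, c("pair_id", "label")], m1[, c("pair_id", "label")])

  # missing counterpart image names the pair
  bad <- m1
  bad$thermal_path[3L] <- file.path(tempdir(), "nope.png")
  badfile <- tempfile(fileext = ".csv")
  write_manifest(bad, badfile)
  expect_error(read_manifest(badfile), "pairing error.*pair_0003")

  # non-binary label is a parse error
  bad2 <- m1
  bad2$label[1L] <- 2L
  badfile2 <- tempfile(fileext = ".csv")
  write_manifest(bad2, badfile2)
  expect_error(read_manifest(badfile2), "parse error")

  # wrong header
  hdr <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c,d", "x,y,z,0"), hdr)
  expect_error(read_manifest(hdr), "header")
  expect_error(read_manifest(tempfile()), "missing manifest")
})

test_that("resize follows the truncating scale rule on the native frame sizes", {
  # 640x480 RGB frame: scale 224/640 = 0.35, content 224x168, 28 px bands
  img <- array(runif(480 * 640 * 3), c(480L, 640L, 3L))
  r <- resize_to_canvas(img, preprocess_config(target_size = 224L))
  expect_equal(r$scale_factor, 0.35)
  expect_equal(dim(r$image), c(3L, 224L, 224L))
  expect_true(all(r$image[, 1:28, ] == 0)) # top pad band
  expect_true(all(r$image[, 197:224, ] == 0)) # bottom pad band
  expect_false(all(r$image[, 29:196, ] == 0))

  # 320x240 thermal frame: scale 224/320 = 0.7, content 224x168
  img2 <- array(runif(240 * 320 * 3), c(240L, 320L, 3L))
  r2 <- resize_to_canvas(img2, preprocess_config(target_size = 224L))
  expect_equal(r2$scale_factor, 0.7)
  expect_true(all(r2$image[, 1:28, ] == 0))

  # integer truncation: 100x37 at target 50 -> new_h = int(37*0.5) = 18
  img3 <- array(runif(37 * 100 * 3), c(37L, 100L, 3L))
  r3 <- resize_to_canvas(img3, preprocess_config(target_size = 50L))
  content_rows <- apply(r3$image[1L, , ] != 0, 1L, any)
  expect_equal(sum(content_rows), 18L)
})

test_that("resize is the identity on already-conforming images", {
  img <- array(runif(224 * 224 * 3), c(224L, 224L, 3L))
  r <- resize_to_canvas(img, preprocess_config(target_size = 224L))
  expect_equal(r$scale_factor, 1.0)
  expect_identical(r$image, aperm(img, c(3L, 1L, 2L)))
  # idempotence through a second pass
  again <- resize_to_canvas(aperm(r$image, c(2L, 3L, 1L)),
                            preprocess_config(target_size = 224L))
  expect_identical(again$image, r$image)
})

test_that("content aspect ratio is preserved within the truncation bound", {
  withr::with_seed(8L, {
    for (i in 1:10) {
      w <- sample(40:300, 1L); h <- sample(40:300, 1L)
      img <- array(runif(h * w * 3), c(h, w, 3L))
      t <- 64L
      r <- resize_to_canvas(img, preprocess_config(target_size = t))
      sf <- t / max(w, h)
      new_w <- as.integer(w * sf); new_h <- as.integer(h * sf)
      expect_equal(max(new_w, new_h), t)
      bound <- (w / h + 1) / min(new_w, new_h)
      expect_lte(abs(new_w / new_h - w / h), bound)
    }
  })
})

test_that("center-crop policy fills the full canvas", {
  img <- array(runif(480 * 640 * 3), c(480L, 640L, 3L))
  r <- resize_to_canvas(img, preprocess_config(target_size = 224L,
                                               canvas_policy = "center_crop"))
  expect_equal(r$scale_factor, 224 / 480)
  expect_equal(dim(r$image), c(3L, 224L, 224L))
  expect_true(all(r$image != 0)) # no pad pixels under crop
})

test_that("normalization follows the channelwise affine rule and inverts", {
  stats <- vit_norm_stats()
  expect_equal(stats$mean, c(0.485, 0.456, 0.406))
  expect_equal(stats$sd, c(0.229, 0.224, 0.225))

  # constant image at the channel means maps to zero
  img <- array(0, c(3L, 4L, 4L))
  for (ch in 1:3) img[ch, , ] <- stats$mean[ch]
  expect_equal(normalize_image(img, stats), array(0, c(3L, 4L, 4L)))

  # hand-computed pixel: (0.714 - 0.485) / 0.229 = 1.0
  img[1L, 1L, 1L] <- 0.714
  expect_equal(normalize_image(img, stats)[1L, 1L, 1L], 1.0,
               tolerance = 1e-12)

  # invertibility
  withr::with_seed(2L, x <- array(runif(3 * 5 * 5), c(3L, 5L, 5L)))
  expect_equal(denormalize_image(normalize_image(x, stats), stats), x,
               tolerance = 1e-6)
  expect_error(norm_stats(c(0, 0, 0), c(1, 0, 1)), "sd")
})

test_that("thermal statistics are estimated per channel with a degenerate fallback", {
  a <- array(0.2, c(3L, 4L, 4L)); b <- array(0.8, c(3L, 4L, 4L))
  st <- estimate_thermal_stats(list(a, b))
  expect_equal(st$mean, rep(0.5, 3L))
  expect_equal(st$source, "dataset_estimated")
  # constant input: sd would be 0; replaced by 1 with a warning
  expect_warning(st0 <- estimate_thermal_stats(list(a, a)), "sd = 0")
  expect_equal(st0$sd, rep(1, 3L))
  expect_error(estimate_thermal_stats(list(a)), "at least 2")
  # reproducibility on the synthetic dataset
  pairs <- small_pairs()
  s1 <- estimate_thermal_stats(lapply(small_dataset()$samples$thermal_path[1:4],
                                      function(p) {
    resize_to_canvas(load_image(p), preprocess_config(32L))$image
  }))
  s2 <- estimate_thermal_stats(lapply(small_dataset()$samples$thermal_path[1:4],
                                      function(p) {
    resize_to_canvas(load_image(p), preprocess_config(32L))$image
  }))
  expect_identical(s1, s2)
})

test_that("preprocessing estimates thermal stats on the training split only", {
  ds <- small_dataset()
  prep <- preprocess_dataset(ds$samples, preprocess_config(target_size = 32L),
                             train_idx = 1:6)
  resized <- lapply(ds$samples$thermal_path[1:6], function(p)
    resize_to_canvas(load_image(p), preprocess_config(32L))$image)
  expect_equal(prep$stats_thermal$mean, estimate_thermal_stats(resized)$mean)
  p1 <- prep$pairs[[1L]]
  expect_s3_class(p1, "preprocessed_pair")
  expect_equal(dim(p1$rgb), c(3L, 32L, 32L))
  expect_equal(dim(p1$thermal), c(3L, 32L, 32L))
  expect_equal(unname(p1$scale_factors["rgb"]), 32 / 64)
})
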