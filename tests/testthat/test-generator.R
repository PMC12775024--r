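test_that("class counts follow the rounding rule and the manifest is complete", {
  ds <- small_dataset(n_pairs = 10L, seed = 7L, key = "counts10")
  expect_equal(sum(ds$samples$label == 0L), 5L) # round(0.5 * 10)
  expect_equal(sum(ds$samples$label == 1L), 5L)
  expect_equal(nrow(ds$samples), 10L)
  expect_true(all(file.exists(ds$samples$rgb_path)))
  expect_true(all(file.exists(ds$samples$thermal_path)))
  # uneven balance
  cfg <- generator_config(n_pairs = 7L, class_balance = 0.6, seed = 2L,
                          rgb_size = c(64L, 48L), thermal_size = c(32L, 24L))
  ds2 <- generate_dataset(cfg, tempfile("gen_"))
  expect_equal(sum(ds2$samples$label == 0L), round(0.6 * 7)) # 4 FAW
})

test_that("identical configs produce byte-identical images and manifest", {
  cfg <- generator_config(n_pairs = 6L, seed = 31L,
                          rgb_size = c(64L, 48L), thermal_size = c(32L, 24L))
  d1 <- generate_dataset(cfg, tempfile("det1_"))
  d2 <- generate_dataset(cfg, tempfile("det2_"))
  files1 <- c(d1$samples$rgb_path, d1$samples$thermal_path, d1$manifest,
              d1$ground_truth)
  files2 <- c(d2$samples$rgb_path, d2$samples$thermal_path, d2$manifest,
              d2$ground_truth)
  expect_identical(md5_of(files1), md5_of(files2))
  # and a different seed changes the images
  cfg3 <- generator_config(n_pairs = 6L, seed = 32L,
                           rgb_size = c(64L, 48L), thermal_size = c(32L, 24L))
  d3 <- generate_dataset(cfg3, tempfile("det3_"))
  expect_false(identical(md5_of(d1$samples$rgb_path),
                         md5_of(d3$samples$rgb_path)))
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(n_pairs = 1L), "n_pairs")
  expect_error(generator_config(n_pairs = 10L, class_balance = 0.01),
               "empty class")
  expect_error(generator_config(class_balance = 1.2), "class_balance")
  expect_error(generator_config(misalignment_px = -1L), "misalignment")
})

test_that("ground truth records masks, offsets and corruption flags", {
  ds <- small_dataset(n_pairs = 12L, seed = 7L)
  gt_all <- lapply(ds$samples$pair_id, generator_ground_truth,
                   dataset = ds)
  labels <- vapply(gt_all, `[[`, integer(1L), "label")
  expect_identical(labels, ds$samples$label)
  for (i in seq_along(gt_all)) {
    gt <- gt_all[[i]]
    if (gt$label == 1L) { # Healthy: empty masks, no offset
      expect_false(any(gt$lesion_mask))
      expect_false(any(gt$hotspot_mask))
      expect_null(gt$offset)
    } else {
      expect_true(any(gt$lesion_mask))
      expect_true(all(abs(gt$offset) <= 6L)) # default misalignment_px
      expect_equal(dim(gt$lesion_mask), c(48L, 64L))
      expect_equal(dim(gt$hotspot_mask), c(24L, 32L))
    }
  }
  expect_error(generator_ground_truth(ds, "pair_9999"), "lookup error")
})

test_that("zero misalignment makes the hotspot mask the downsampled lesion mask", {
  cfg <- generator_config(n_pairs = 6L, seed = 13L, misalignment_px = 0L,
                          rgb_size = c(64L, 48L), thermal_size = c(32L, 24L))
  ds <- generate_dataset(cfg, tempfile("offset0_"))
  faw <- ds$samples$pair_id[ds$samples$label == 0L]
  ns <- asNamespace("fawfusion")
  for (id in faw) {
    gt <- generator_ground_truth(ds, id)
    expect_identical(gt$offset, c(0L, 0L))
    down <- ns$downsample_translate_mask(gt$lesion_mask, 24L, 32L, 0L, 0L)
    expect_identical(gt$hotspot_mask, down)
  }
})

test_that("occluded RGB carries no lesion cue while thermal contrast persists", {
  cfg <- generator_config(n_pairs = 30L, seed = 41L,
                          rgb_occlusion_prob = 1, thermal_degrade_prob = 0,
                          noise_sd = 0.03,
                          rgb_size = c(96L, 64L), thermal_size = c(48L, 32L))
  ds <- generate_dataset(cfg, tempfile("occl_"))
  lesion_vals <- c(); bg_vals <- c(); contrasts <- c()
  for (i in seq_len(nrow(ds$samples))) {
    id <- ds$samples$pair_id[i]
    gt <- generator_ground_truth(ds, id)
    if (gt$label != 0L) next
    expect_true(gt$occluded)
    rgb <- load_image(ds$samples$rgb_path[i])
    g <- rgb[, , 2L]
    lesion_vals <- c(lesion_vals, mean(g[gt$lesion_mask]))
    bg_vals <- c(bg_vals, mean(g[!gt$lesion_mask]))
    th <- load_image(ds$samples$thermal_path[i])[, , 1L]
    contrasts <- c(contrasts,
                   mean(th[gt$hotspot_mask]) - mean(th[!gt$hotspot_mask]))
  }
  # occluded lesions are statistically indistinguishable from background
  expect_gt(stats::t.test(lesion_vals, bg_vals)$p.value, 0.01)
  # thermal hotspots retain at least half the configured gain
  expect_true(all(contrasts > cfg$hotspot_gain / 2))
})

test_that("occlusion and degradation are independent with rate p*q", {
  cfg <- generator_config(n_pairs = 500L, seed = 77L,
                          rgb_occlusion_prob = 0.25,
                          thermal_degrade_prob = 0.25,
                          rgb_size = c(32L, 32L), thermal_size = c(16L, 16L),
                          lesion_count_range = c(1L, 2L))
  ds <- generate_dataset(cfg, tempfile("compl_"))
  faw_ids <- ds$samples$pair_id[ds$samples$label == 0L]
  both <- vapply(faw_ids, function(id) {
    gt <- generator_ground_truth(ds, id)
    gt$occluded && gt$degraded
  }, logical(1L))
  bt <- stats::binom.test(sum(both), length(both), p = 0.25 * 0.25)
  expect_gt(bt$p.value, 0.001)
})

test_that("written rasters stay within the valid intensity range", {
  ds <- small_dataset(n_pairs = 12L, seed = 7L)
  for (f in c(ds$samples$rgb_path[1:3], ds$samples$thermal_path[1:3])) {
    img <- load_image(f)
    expect_true(all(img >= 0 & img <= 1))
    expect_equal(dim(img)[3L], 3L)
  }
})

test_that("run-length mask encoding round-trips", {
  ns <- asNamespace("fawfusion")
  withr::with_seed(4L, {
    for (i in 1:10) {
      m <- matrix(runif(15 * 11) < 0.3, 15, 11)
      expect_identical(ns$rle_decode_mask(ns$rle_encode_mask(m)), m)
    }
  })
  empty <- matrix(FALSE, 4L, 5L)
  expect_identical(ns$rle_decode_mask(ns$rle_encode_mask(empty)), empty)
})
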