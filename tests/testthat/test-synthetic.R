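test_that("generation is deterministic and validates its arguments", {
  cfg <- tiny_config(size = 32, n_classes = 3, artifact_rate = 0.5)
  a <- generate_sample(cfg, 2, seed = 42)
  b <- generate_sample(cfg, 2, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_error(generate_sample(cfg, 4, seed = 1), "out of range")
  expect_error(generate_sample(cfg, 0, seed = 1), "out of range")
  expect_error(synthetic_config(lesion_radius_range = c(0.1, 0.6)), "0.5")
  expect_error(synthetic_config(artifact_rate = 1.2), "artifact_rate")
})

test_that("artifact_rate zero yields artifact-free images, positive rates paint pixels", {
  cfg0 <- tiny_config(size = 32, n_classes = 3, artifact_rate = 0)
  sm0 <- generate_sample(cfg0, 1, seed = 7)
  expect_false(sm0$has_hair || sm0$has_droplet)
  expect_length(sm0$artifact_idx, 0)
  # same seed, artifact_rate 1: identical outside the painted pixels
  cfg1 <- tiny_config(size = 32, n_classes = 3, artifact_rate = 1)
  sm1 <- generate_sample(cfg1, 1, seed = 7)
  expect_true(sm1$has_hair && sm1$has_droplet)
  expect_gt(length(sm1$artifact_idx), 0)
  keep <- setdiff(seq_len(32 * 32), sm1$artifact_idx)
  for (c in 1:3) {
    expect_equal(sm1$image[, , c][keep], sm0$image[, , c][keep])
  }
  expect_identical(sm1$mask, sm0$mask) # artifacts never touch the mask
})

test_that("mask area tracks the analytic ellipse area", {
  cfg <- synthetic_config(image_height = 224, image_width = 224, n_classes = 3,
                          class_palette = default_class_palette(3),
                          lesion_radius_range = c(0.2, 0.2),
                          artifact_rate = 0, seed = 1)
  target <- pi * (0.2 * 224)^2
  for (s in 1:5) {
    sm <- generate_sample(cfg, 1, seed = s)
    expect_lt(abs(sum(sm$mask) - target) / target, 0.15)
  }
})

test_that("datasets are balanced, deterministic per seed and distinct across seeds", {
  cfg <- tiny_config(size = 16, n_classes = 7, seed = 5)
  cfg$class_palette <- default_class_palette(7)
  ds <- generate_dataset(cfg, 3)
  expect_length(ds$samples, 21)
  expect_equal(as.vector(table(ds$manifest$label)), rep(3, 7))
  ds2 <- generate_dataset(cfg, 3)
  expect_identical(ds$samples[[5]]$image, ds2$samples[[5]]$image)
  cfg_b <- cfg; cfg_b$seed <- 6L
  ds3 <- generate_dataset(cfg_b, 3)
  expect_false(identical(ds$samples[[1]]$image, ds3$samples[[1]]$image))
  expect_equal(ds$manifest$label, ds3$manifest$label)
})

test_that("per-class mean lesion colors separate by more than three noise sds", {
  cfg <- tiny_config(size = 32, n_classes = 7, seed = 8, noise_sd = 0.05)
  cfg$class_palette <- default_class_palette(7)
  means <- t(vapply(1:7, function(ci) {
    sms <- lapply(1:6, function(i) generate_sample(cfg, ci, seed = 100 * ci + i))
    cols <- t(vapply(sms, function(sm) {
      idx <- sm$mask == 1
      c(mean(sm$image[, , 1][idx]), mean(sm$image[, , 2][idx]),
        mean(sm$image[, , 3][idx]))
    }, numeric(3)))
    colMeans(cols)
  }, numeric(3)))
  dmin <- min(stats::dist(means))
  expect_gt(dmin, 3 * cfg$noise_sd)
})

test_that("offline augmentation preserves labels, masks and counts", {
  cfg <- tiny_config(size = 32, n_classes = 3, seed = 3)
  ds <- generate_dataset(cfg, 2)
  # identity transform family reproduces the inputs
  out <- offline_augment(ds$samples, rotation_range_deg = c(0, 0),
                         flip_horizontal = FALSE, flip_vertical = FALSE,
                         copies_per_sample = 1, seed = 1)
  expect_length(out, 12)
  expect_identical(out[[2]]$image, ds$samples[[1]]$image)
  # full family: masks stay binary and labels survive
  out2 <- offline_augment(ds$samples, copies_per_sample = 2, seed = 2)
  expect_length(out2, 18)
  for (sm in out2) {
    expect_true(all(sm$mask %in% c(0, 1)))
    expect_true(sm$label %in% 1:3)
    expect_true(all(sm$image >= 0 & sm$image <= 1))
  }
  expect_identical(offline_augment(list()), list())
})

test_that("augmented masks co-transform with the lesion support", {
  cfg <- tiny_config(size = 64, n_classes = 3, seed = 4, noise_sd = 0)
  sm <- generate_sample(cfg, 1, seed = 10)
  out <- offline_augment(list(sm), copies_per_sample = 3, seed = 6)
  pal <- cfg$class_palette[1, ]
  for (aug in out[-1]) {
    # lesion pixels are darker than skin for class 1; the transformed mask
    # should still cover the dark region almost exactly
    lum <- apply(aug$image, c(1, 2), mean)
    dark <- (lum < 0.5) * 1
    if (sum(dark) > 0) {
      expect_gte(dice(mask_overlap(aug$mask, dark)), 0.9)
    }
  }
})

test_that("datasets round-trip through PNG files and a CSV manifest", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(size = 16, n_classes = 3, seed = 2)
  ds <- generate_dataset(cfg, 2)
  manifest <- write_dataset(ds, dir)
  expect_setequal(names(manifest),
                  c("sample_id", "label", "image_path", "mask_path"))
  back <- read_dataset(dir)
  expect_length(back, 6)
  expect_equal(back[[3]]$label, ds$samples[[3]]$label)
  expect_identical(back[[3]]$mask, ds$samples[[3]]$mask)
  # PNG quantizes to 8 bits
  expect_equal(back[[3]]$image, ds$samples[[3]]$image, tolerance = 1 / 255)
})
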