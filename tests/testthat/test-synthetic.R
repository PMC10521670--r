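test_that("sample generation is counter-based and bit-reproducible", {
  cfg <- synth_domain_config("det", "ellipse_ring", 5L, seed = 9L)
  a <- generate_sample(cfg, 3L)
  b <- generate_sample(cfg, 3L)
  expect_identical(a$image, b$image)
  expect_identical(a$landmarks, b$landmarks)
  # independent of generation order
  generate_sample(cfg, 0L)
  c_ <- generate_sample(cfg, 3L)
  expect_identical(c_$image, a$image)
  # different indices differ
  expect_false(identical(generate_sample(cfg, 4L)$image, a$image))
  # the global RNG stream is left untouched
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(generate_sample(cfg, 1L)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("zero jitter and noise place landmarks at analytic loci", {
  cfg <- synth_domain_config("canon", "ellipse_ring", 5L,
                             jitter = list(scale = 0, rotate = 0,
                                           translate = 0),
                             texture_noise_sd = 0)
  s <- generate_sample(cfg, 0L)
  ctr <- c(31.5, 31.5)
  R0 <- 0.3 * 64
  a <- R0; b <- 0.72 * R0
  expected <- rbind(ctr + c(a, 0), ctr + c(0, b), ctr - c(a, 0),
                    ctr - c(0, b), ctr)
  expect_equal(unname(s$landmarks), unname(expected), tolerance = 1e-9)
  # the ring's brightest pixels trace the ellipse: the axis-endpoint pixel
  # is bright, the centre is dark
  expect_gt(s$image[32, round(ctr[1] + a) + 1], 0.8)
  expect_lt(s$image[32, 32], 0.3)
})

test_that("every family renders n landmarks inside the safety margin", {
  fams <- c("ellipse_ring", "digit_fan", "twin_lobes", "arch_pair")
  counts <- c(5L, 9L, 4L, 10L)
  for (i in seq_along(fams)) {
    cfg <- synth_domain_config(fams[i], fams[i], counts[i], seed = 3L + i)
    for (idx in c(0L, 7L, 91L)) {
      s <- generate_sample(cfg, idx)
      expect_equal(nrow(s$landmarks), counts[i])
      expect_true(all(s$landmarks >= 8 & s$landmarks <= 55))
      expect_gt(stats::sd(s$image), 0.02)  # something was rendered
    }
  }
})

test_that("jitter spreads landmarks consistently with the configured ranges", {
  cfg <- synth_domain_config("jit", "twin_lobes", 4L, seed = 21L)
  pos <- t(vapply(0:299, function(i)
    generate_sample(cfg, i)$landmarks[1L, ], numeric(2L)))
  canon <- generate_sample(synth_domain_config(
    "jit", "twin_lobes", 4L,
    jitter = list(scale = 0, rotate = 0, translate = 0),
    texture_noise_sd = 0), 0L)$landmarks[1L, ]
  dev <- sweep(pos, 2L, canon)
  # jitter must genuinely move the landmarks ...
  expect_gt(stats::sd(dev[, 1L]), 0.5)
  expect_gt(stats::sd(dev[, 2L]), 0.5)
  # ... centred near the canonical locus ...
  expect_lt(abs(mean(dev[, 1L])), 1.5)
  expect_lt(abs(mean(dev[, 2L])), 1.5)
  # ... and bounded by the worst-case affine displacement
  r <- sqrt(sum((canon - 31.5)^2))
  worst <- 0.08 * r + r * (10 * pi / 180) + 4 * sqrt(2) + 1e-9
  expect_true(all(sqrt(rowSums(dev^2)) <= worst))
})

test_that("the default benchmark has 3 domains, 600 training images", {
  bm <- generate_benchmark(seed = 2L)
  expect_equal(registry_size(bm$registry), 3L)
  expect_equal(bm$domains$num_landmarks, c(5L, 9L, 4L))
  expect_equal(sum(vapply(bm$train, length, integer(1L))), 600L)
  expect_equal(vapply(bm$test, length, integer(1L)),
               c("0" = 40L, "1" = 40L, "2" = 40L))
  # per-domain landmark counts differ, exercising per-domain heads
  expect_equal(length(unique(bm$domains$num_landmarks)), 3L)
  # regeneration under the same seed is bit-identical
  bm2 <- generate_benchmark(seed = 2L)
  expect_identical(bm$train[["1"]][[17L]]$image,
                   bm2$train[["1"]][[17L]]$image)
  # the equal-landmark pair preset supports full parameter swaps
  pair <- synth_benchmark_configs("pair2")
  expect_equal(vapply(pair, `[[`, integer(1L), "num_landmarks"),
               c(5L, 5L))
})

test_that("written benchmarks reload through the registry and sample loaders", {
  cfgs <- list(synth_domain_config("tiny-ring", "ellipse_ring", 4L,
                                   n_train = 2L, n_val = 1L, n_test = 1L,
                                   seed = 33L))
  bm <- generate_benchmark(cfgs, seed = 1L)
  dir <- withr::local_tempdir()
  write_benchmark(bm, dir)
  reg <- register_domains(file.path(dir, "registry.yaml"))
  expect_equal(registry_size(reg), 1L)
  spec <- reg[["tiny-ring"]]
  s0 <- bm$train[["0"]][[1L]]
  base <- file.path(dir, "tiny-ring", "train", s0$source_id)
  re <- load_sample(paste0(base, ".png"), paste0(base, ".csv"), spec)
  expect_equal(re$landmarks, s0$landmarks, tolerance = 1e-6)
  expect_lt(max(abs(re$image - pmin(pmax(s0$image, 0), 1))), 1 / 255)
})

test_that("shape families are separable by a trivial histogram classifier", {
  skip_if_not_installed("MASS")
  fams <- c("ellipse_ring", "digit_fan", "twin_lobes", "arch_pair")
  feats <- function(img) {
    v <- pmin(pmax(as.numeric(img), 0), 1)
    p <- as.numeric(graphics::hist(v, breaks = seq(0, 1, by = 1 / 12),
                                   plot = FALSE)$counts) / length(v)
    p[-12L]   # proportions sum to 1; drop one to avoid collinearity
  }
  tr <- list(); te <- list()
  for (i in seq_along(fams)) {
    cfg <- synth_domain_config(fams[i], fams[i], 4L, seed = 50L + i)
    tr[[i]] <- t(vapply(0:39, function(k)
      feats(generate_sample(cfg, k)$image), numeric(11L)))
    te[[i]] <- t(vapply(40:64, function(k)
      feats(generate_sample(cfg, k)$image), numeric(11L)))
  }
  X <- do.call(rbind, tr)
  y <- factor(rep(fams, each = 40L))
  fit <- MASS::lda(X, grouping = y)
  Xt <- do.call(rbind, te)
  yt <- factor(rep(fams, each = 25L))
  acc <- mean(predict(fit, Xt)$class == yt)
  expect_gte(acc, 0.95)
})

test_that("a separable network overfits ten images to the entropy floor", {
  # soft Gaussian targets carry an irreducible cross-entropy H(Y) even for
  # a perfect prediction, so overfitting is measured as the excess loss
  # above that floor shrinking to a few percent of its starting value
  cfg <- synth_domain_config("ofit", "ellipse_ring", 4L,
                             jitter = list(scale = 0.05, rotate = 5,
                                           translate = 2),
                             n_train = 10L, n_val = 2L, n_test = 2L,
                             seed = 88L)
  bm <- generate_benchmark(list(cfg), seed = 1L)
  floor_ <- mean(vapply(bm$train[["0"]], function(s) {
    tgt <- uniland:::.encode_map(s$landmarks, 64L, 64L, 3)
    heatmap_bce_loss(tgt, tgt)
  }, numeric(1L)))
  net <- network_config(bm$domains, encoder_widths = c(16L, 32L, 48L, 64L),
                        global_width = 8L, variant = "local_only",
                        seed = 10L)
  # 10 images, batch 4 -> 2 steps/epoch; 100 epochs = 200 steps; a flat
  # learning rate suits a pure memorization check
  tc <- train_config(epochs = 100L, seed = 20L, lr_max = 5e-3,
                     lr_min = 4e-3, cycle_epochs = 100L,
                     augmentation = augment_config(rotate_prob = 0,
                                                   translate_prob = 0))
  fit <- train_model(build_model(net), bm$train, bm$val, tc)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)] - floor_,
            0.05 * (h$train_loss[1L] - floor_))
})
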