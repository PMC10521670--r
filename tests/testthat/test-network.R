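test_that("separable-block parameter formula and standard comparison", {
  expect_equal(count_separable_params(4, 64, 64), 6400)
  expect_equal(count_standard_params(4, 64, 64), 9 * 4 * 64 * 64)
  expect_equal(count_separable_params(1, 8, 16), 9 * 8 + 8 * 16)
  expect_error(count_separable_params(0, 8, 8), "positive")
})

test_that("formula count matches exhaustive weight enumeration per block", {
  cfg <- tiny_config()
  model <- build_model(cfg)
  t_ <- nrow(cfg$domains)
  plan <- uniland:::.block_plan(cfg$encoder_widths,
                                cfg$domains$input_channels[1L])
  for (i in seq_len(nrow(plan))) {
    b <- plan[i, ]
    dw_total <- sum(vapply(cfg$domains$domain_id, function(d)
      length(model$params[[paste0("dom", d, ".", b$name, ".dw.W")]]),
      integer(1L)))
    pw_total <- length(model$params[[paste0("shared.", b$name, ".pw.W")]])
    expect_equal(dw_total + pw_total,
                 count_separable_params(t_, b$cin, b$cout))
  }
})

test_that("forward produces per-landmark maps in (0,1) with correct shape", {
  model <- build_model(tiny_config())
  img <- rand_image(32, 32)
  out <- predict_heatmaps(model, img, 0L)
  expect_equal(dim(out$final$values), c(32L, 32L, 2L))
  out1 <- predict_heatmaps(model, img, 1L)
  expect_equal(dim(out1$final$values), c(32L, 32L, 3L))
  for (role in c("local", "global", "final")) {
    expect_gte(min(out[[role]]$values), 0)
    expect_lte(max(out[[role]]$values), 1)
  }
  lm <- predict_landmarks(model, img, 0L)
  expect_equal(dim(lm), c(2L, 2L))
  expect_error(predict_heatmaps(model, img, 7L), "unknown domain")
  expect_error(predict_heatmaps(model, rand_image(30, 32), 0L),
               "divisible by 16")
})

test_that("a single-domain config collapses to a plain separable U-Net", {
  model <- build_model(tiny_config(landmarks = 4L))
  out <- predict_heatmaps(model, rand_image(32, 32), 0L)
  expect_equal(dim(out$final$values)[3L], 4L)
  pp <- partition_params(model)
  expect_length(pp$per_domain, 1L)
  expect_gt(pp$counts$shared, 0L)
})

test_that("separable-block backward matches finite differences exactly", {
  # the block is checked in isolation so central differences are not
  # polluted by kinks of downstream rectifiers and pooling argmaxes
  set.seed(55)
  H <- 8L; W <- 10L; N <- 2L; Cin <- 3L; Cout <- 4L
  P <- N * H * W
  params <- list(
    "dom0.tb.dw.W" = matrix(rnorm(Cin * 9, sd = 0.5), Cin, 9L),
    "dom0.tb.bn1.gamma" = runif(Cin, 0.5, 1.5),
    "dom0.tb.bn1.beta" = rnorm(Cin, sd = 0.3),
    "shared.tb.pw.W" = matrix(rnorm(Cout * Cin, sd = 0.5), Cout, Cin),
    "shared.tb.pw.b" = rnorm(Cout, sd = 0.3),
    "shared.tb.bn2.gamma" = runif(Cout, 0.5, 1.5),
    "shared.tb.bn2.beta" = rnorm(Cout, sd = 0.3)
  )
  X <- matrix(rnorm(Cin * P), Cin, P)
  G <- matrix(rnorm(Cout * P), Cout, P)   # random output cotangent
  run <- function(p, x) {
    st <- uniland:::.new_state()
    sum(uniland:::.sep_fwd(p, st, "tb", 0L, x, H, W, N,
                           training = TRUE, slope = 0.01)$y * G)
  }
  st <- uniland:::.new_state()
  fw <- uniland:::.sep_fwd(params, st, "tb", 0L, X, H, W, N,
                           training = TRUE, slope = 0.01, keep = TRUE)
  gacc <- uniland:::.gnew()
  dX <- uniland:::.sep_bwd(params, G, fw$cache, gacc, 0.01)
  gr <- uniland:::.gas_list(gacc)
  # the point-wise bias feeds straight into batch norm, which subtracts
  # the batch mean: its true gradient is identically zero
  expect_lt(max(abs(gr[["shared.tb.pw.b"]])), 1e-8)
  eps <- 1e-6
  for (nm in setdiff(names(params), "shared.tb.pw.b")) {
    set.seed(nchar(nm))
    for (i in sample(length(params[[nm]]), min(3L, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- run(p2, X)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l2 <- run(p2, X)
      num <- (l1 - l2) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(abs(num), abs(gr[[nm]][i]), 1e-6), 1e-4)
    }
  }
  # input gradient too
  for (i in c(1L, 57L, 300L)) {
    x2 <- X
    x2[i] <- x2[i] + eps
    l1 <- run(params, x2)
    x2[i] <- x2[i] - 2 * eps
    l2 <- run(params, x2)
    num <- (l1 - l2) / (2 * eps)
    expect_lt(abs(num - dX[i]) / max(abs(num), abs(dX[i]), 1e-6), 1e-4)
  }
})

test_that("whole-network backward matches finite differences on smooth paths", {
  # tensors whose loss path avoids rectifier kinks (output heads and the
  # last global convolution feed sigmoids only), so central differences
  # are trustworthy end to end
  model <- build_model(tiny_config(seed = 7L))
  set.seed(13)
  X <- matrix(rnorm(2 * 32 * 32), 1L, 2L * 32L * 32L)
  Tg <- matrix(runif(2 * 2 * 32 * 32), 2L, 2L * 32L * 32L)
  fw <- uniland:::.forward_net(model, X, 32L, 32L, 2L, 0L,
                               training = TRUE, keep = TRUE)
  gr <- uniland:::.backward_net(model, fw,
                                uniland:::.bce_grad(fw$final, Tg, 2L))
  fd <- function(nm, i, eps = 1e-6) {
    m2 <- model
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    l1 <- heatmap_bce_loss(uniland:::.forward_net(
      m2, X, 32L, 32L, 2L, 0L, training = TRUE)$final, Tg, n_batch = 2L)
    m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
    l2 <- heatmap_bce_loss(uniland:::.forward_net(
      m2, X, 32L, 32L, 2L, 0L, training = TRUE)$final, Tg, n_batch = 2L)
    (l1 - l2) / (2 * eps)
  }
  for (nm in c("dom0.head.W", "dom0.head.b", "dom0.glob5.W",
               "dom0.glob5.b")) {
    i <- which.max(abs(gr[[nm]]))
    num <- fd(nm, i)
    expect_lt(abs(num - gr[[nm]][i]) / max(abs(num), abs(gr[[nm]][i])),
              1e-5)
  }
})

test_that("routing isolates per-domain parameters and trains shared ones", {
  model <- build_model(tiny_config(seed = 3L))
  set.seed(5)
  X <- matrix(rnorm(32 * 32), 1L, 32L * 32L)
  Tg <- matrix(runif(2 * 32 * 32), 2L, 32L * 32L)
  fw <- uniland:::.forward_net(model, X, 32L, 32L, 1L, 0L,
                               training = TRUE, keep = TRUE)
  gr <- uniland:::.backward_net(model, fw,
                                uniland:::.bce_grad(fw$final, Tg, 1L))
  # gradients exist only for domain 0 and shared tensors
  expect_false(any(startsWith(names(gr), "dom1.")))
  expect_true(any(startsWith(names(gr), "dom0.")))
  expect_true(any(startsWith(names(gr), "shared.")))
  # an optimizer step changes domain 0 + shared, leaves domain 1 bit-exact
  before <- model$params
  opt <- uniland:::.adam_new()
  model$params <- uniland:::.adam_step(model$params, gr, opt, 1e-3)
  d1 <- names(before)[startsWith(names(before), "dom1.")]
  expect_identical(model$params[d1], before[d1])
  expect_false(identical(model$params[["shared.enc0a.pw.W"]],
                         before[["shared.enc0a.pw.W"]]))
  expect_false(identical(model$params[["dom0.head.W"]],
                         before[["dom0.head.W"]]))
})

test_that("initialization and forward are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 99L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  img <- rand_image(32, 32, seed = 2L)
  expect_identical(predict_heatmaps(m1, img, 1L)$final$values,
                   predict_heatmaps(m2, img, 1L)$final$values)
})

test_that("parameter partition is disjoint, exhaustive, and counted", {
  model <- build_model(tiny_config())
  pp <- partition_params(model)
  all_assigned <- c(pp$shared, unlist(pp$per_domain, use.names = FALSE))
  expect_setequal(all_assigned, names(model$params))
  expect_false(anyDuplicated(all_assigned) > 0)
  expect_equal(pp$counts$shared + sum(pp$counts$per_domain),
               pp$counts$total)
  expect_equal(pp$counts$total, n_params(model))
})

test_that("the baseline U-Net has only shared parameters and a union head", {
  cfg <- tiny_config(landmarks = c(2L, 3L))
  bl <- build_unet_baseline(cfg)
  pp <- partition_params(bl)
  expect_length(pp$per_domain, 0L)
  expect_equal(pp$counts$shared, n_params(bl))
  expect_equal(nrow(bl$params[["shared.head.W"]]), 5L)  # union of channels
  out <- predict_heatmaps(bl, rand_image(32, 32), 1L)
  expect_equal(dim(out$final$values), c(32L, 32L, 3L))
})

test_that("local-only ablation fuses against an all-ones global map", {
  model <- build_model(tiny_config(variant = "local_only"))
  out <- predict_heatmaps(model, rand_image(32, 32), 0L)
  expect_equal(min(out$global$values), 1)
  expect_identical(out$final$values, out$local$values)
})

test_that("domain swaps are involutions and respect shape compatibility", {
  model <- build_model(tiny_config(landmarks = c(3L, 3L)))
  # identity swap
  expect_identical(swap_domain_params(model, 0L, 0L)$params, model$params)
  # double swap restores the model bit-exactly (equal landmark counts:
  # every tensor including heads participates)
  sw <- swap_domain_params(model, 0L, 1L)
  expect_length(attr(sw, "skipped"), 0L)
  expect_false(identical(sw$params[["dom0.head.W"]],
                         model$params[["dom0.head.W"]]))
  back <- swap_domain_params(sw, 0L, 1L)
  expect_identical(back$params, model$params)
  # unequal landmark counts: output-shaped tensors are excluded, reported
  m2 <- build_model(tiny_config(landmarks = c(2L, 3L)))
  sw2 <- swap_domain_params(m2, 0L, 1L)
  expect_true("head.W" %in% attr(sw2, "skipped"))
  expect_identical(sw2$params[["dom0.head.W"]],
                   m2$params[["dom0.head.W"]])
  expect_false(identical(sw2$params[["dom0.enc0b.dw.W"]],
                         m2$params[["dom0.enc0b.dw.W"]]))
  # shared parameters are untouched by any swap
  sh <- partition_params(m2)$shared
  expect_identical(sw2$params[sh], m2$params[sh])
})

test_that("the dilated global stack sees a 23x23 window at working scale", {
  expect_equal(global_receptive_field(c(1, 2, 5, 2, 1)), 23L)
  # forward-influence probe: chain the convolution primitive with all-ones
  # kernels (a linearized network) and measure the footprint of a delta
  H <- 33L; W <- 33L
  x <- matrix(0, 1L, H * W)
  x[1L, 16L * W + 16L + 1L] <- 1     # delta at the centre (x=16, y=16)
  ones <- matrix(1, 1L, 9L)
  for (dil in c(1L, 2L, 5L, 2L, 1L))
    x <- ones %*% uniland:::cpp_im2col3(x, H, W, 1L, dil)
  img <- t(matrix(as.numeric(x), W, H))
  on_rows <- range(which(rowSums(img) > 0))
  on_cols <- range(which(colSums(img) > 0))
  expect_equal(diff(on_rows) + 1L, 23L)
  expect_equal(diff(on_cols) + 1L, 23L)
  # five dilated convolutions per domain in the built model
  model <- build_model(tiny_config())
  globs <- grep("^dom0\\.glob[0-9]+\\.W$", names(model$params), value = TRUE)
  expect_length(globs, 5L)
})

test_that("checkpoints round-trip through disk with an introspectable manifest", {
  model <- build_model(tiny_config(seed = 31L))
  dir <- withr::local_tempdir()
  save_checkpoint(model, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_params, n_params(model))
  expect_equal(man$variant, "gu2net")
  re <- load_checkpoint(dir)
  expect_identical(re$params, model$params)
  img <- rand_image(32, 32, seed = 8L)
  expect_identical(predict_heatmaps(re, img, 0L)$final$values,
                   predict_heatmaps(model, img, 0L)$final$values)
})
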