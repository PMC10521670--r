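# Seeded generator of visually distinct pseudo-anatomies with exact
# analytic ground-truth landmarks. Four parametric shape families stand in
# for head/hand/chest/pelvis radiographs so training, evaluation, and all
# experiments run with no external data.
#
# Landmarks are defined on the analytic shape *before* rasterization and
# transformed with the same per-index affine jitter as the rendering, so
# ground truth is exact real-valued coordinates. Randomness is counter
# based: each (config, index) pair derives its own RNG seed, making every
# sample reproducible independently of generation order.

#' Synthetic domain configuration
#'
#' @param name Domain name.
#' @param shape_family One of `"ellipse_ring"` (pseudo-skull: a bright
#'   elliptical ring), `"digit_fan"` (pseudo-hand: a fan of bright rays),
#'   `"twin_lobes"` (pseudo-chest: two filled lobes), `"arch_pair"`
#'   (pseudo-pelvis: two bright arches).
#' @param num_landmarks Landmarks per image, placed at named geometric loci
#'   of the family (extrema, tips, arc points).
#' @param image_size `c(width, height)`, divisible by 16 (default 64x64).
#' @param jitter Affine jitter ranges: `scale` (fractional, +/-), `rotate`
#'   (degrees, +/-), `translate` (px, +/-).
#' @param texture_noise_sd Additive Gaussian intensity noise (image scale
#'   is `[0, 1]`).
#' @param n_train,n_val,n_test Split sizes.
#' @param seed Base seed of the domain's counter-based stream.
#' @return A `synth_domain_config`.
#' @export
synth_domain_config <- function(name, shape_family, num_landmarks,
                                image_size = c(64L, 64L),
                                jitter = list(scale = 0.08, rotate = 10,
                                              translate = 4),
                                texture_noise_sd = 0.08,
                                n_train = 200L, n_val = 20L, n_test = 40L,
                                seed = 1L) {
  shape_family <- match.arg(shape_family,
                            c("ellipse_ring", "digit_fan", "twin_lobes",
                              "arch_pair"))
  image_size <- as.integer(image_size)
  if (any(image_size %% 16L != 0L))
    stop("image_size must be divisible by 16")
  if (num_landmarks < 3L) stop("families need at least 3 landmarks")
  structure(list(name = name, shape_family = shape_family,
                 num_landmarks = as.integer(num_landmarks),
                 image_size = image_size, jitter = jitter,
                 texture_noise_sd = texture_noise_sd,
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "synth_domain_config")
}

# canonical landmark loci (origin at image centre, y down) and intensity
# renderer of each family; R0 is the base radius in px
.family_geometry <- function(family, n, R0) {
  switch(family,
    ellipse_ring = {
      a <- R0; b <- 0.72 * R0
      ang <- 2 * pi * (seq_len(n - 1L) - 1L) / (n - 1L)
      loci <- rbind(cbind(a * cos(ang), b * sin(ang)), c(0, 0))
      render <- function(u, v) {
        d <- sqrt((u / a)^2 + (v / b)^2)
        exp(-((d - 1) * b)^2 / (2 * 2.2^2))
      }
      list(loci = loci, render = render)
    },
    digit_fan = {
      k <- max(2L, floor(n / 2))
      base <- c(0, 0.75 * R0)
      ang <- -pi / 2 + seq(-50, 50, length.out = k) * pi / 180
      len <- R0 * (0.85 + 0.45 * sin(pi * (seq_len(k) - 0.5) / k))
      tips <- cbind(base[1L] + len * cos(ang), base[2L] + len * sin(ang))
      mids <- cbind((base[1L] + tips[, 1L]) / 2, (base[2L] + tips[, 2L]) / 2)
      loci <- rbind(tips, mids, base)[seq_len(n), , drop = FALSE]
      render <- function(u, v) {
        acc <- 0
        for (r in seq_len(k)) {
          px <- u - base[1L]; py <- v - base[2L]
          ex <- tips[r, 1L] - base[1L]; ey <- tips[r, 2L] - base[2L]
          tt <- pmin(pmax((px * ex + py * ey) / (ex^2 + ey^2), 0), 1)
          d2 <- (px - tt * ex)^2 + (py - tt * ey)^2
          acc <- pmax(acc, exp(-d2 / (2 * 1.3^2)))
        }
        acc
      }
      list(loci = loci, render = render)
    },
    twin_lobes = {
      cx <- 0.5 * R0; a <- 0.4 * R0; b <- 0.62 * R0
      loci_all <- rbind(
        c(-cx, -b), c(cx, -b),        # lobe tops
        c(-cx, b), c(cx, b),          # lobe bottoms
        c(-cx, 0), c(cx, 0),          # lobe centres
        c(-cx - a, 0), c(cx + a, 0),  # outer extrema
        c(-cx + a, 0), c(cx - a, 0)   # inner extrema
      )
      loci <- loci_all[seq_len(n), , drop = FALSE]
      render <- function(u, v) {
        d1 <- sqrt(((u + cx) / a)^2 + (v / b)^2)
        d2 <- sqrt(((u - cx) / a)^2 + (v / b)^2)
        pmax(stats::plogis((1 - d1) / 0.06), stats::plogis((1 - d2) / 0.06))
      }
      list(loci = loci, render = render)
    },
    arch_pair = {
      cx <- 0.52 * R0; cy <- 0.15 * R0; r <- 0.48 * R0
      nl <- ceiling(n / 2); nr <- n - nl
      phi_l <- seq(200, 340, length.out = nl) * pi / 180
      phi_r <- seq(200, 340, length.out = nr) * pi / 180
      loci <- rbind(
        cbind(-cx + r * cos(phi_l), cy + r * sin(phi_l)),
        cbind(cx + r * cos(phi_r), cy + r * sin(phi_r))
      )
      dense <- seq(200, 340, length.out = 80L) * pi / 180
      arcs <- rbind(
        cbind(-cx + r * cos(dense), cy + r * sin(dense)),
        cbind(cx + r * cos(dense), cy + r * sin(dense))
      )
      render <- function(u, v) {
        # broad bone-like strokes, clearly wider than the digit_fan rays
        acc <- 0
        for (q in seq_len(nrow(arcs))) {
          d2 <- (u - arcs[q, 1L])^2 + (v - arcs[q, 2L])^2
          acc <- pmax(acc, exp(-d2 / (2 * 2.8^2)))
        }
        acc
      }
      list(loci = loci, render = render)
    }
  )
}

# derived seed of a counter-based stream (independent of generation order)
.sample_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 + 12345) %%
               2147483647)
}

#' Generate one synthetic sample
#'
#' Renders the domain's shape family under a per-index random affine jitter
#' (scale, rotation, translation) drawn from a counter-based stream seeded
#' by `(seed, index)`, places the landmarks at the family's analytic loci
#' transformed by the same affine map, then adds intensity noise. Jitters
#' that would push a landmark within the safety margin of the border are
#' redrawn (bounded retries). The same `(config, index)` always yields a
#' bit-identical sample.
#'
#' @param config A [synth_domain_config()].
#' @param index Sample index (>= 0); the benchmark uses disjoint index
#'   ranges for train/val/test.
#' @param domain_id Domain id to stamp on the sample (default 0).
#' @return A [landmark_sample()] with pixel spacing.
#' @export
generate_sample <- function(config, index, domain_id = 0L) {
  stopifnot(inherits(config, "synth_domain_config"), index >= 0L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.sample_seed(config$seed, index))
  W <- config$image_size[1L]; H <- config$image_size[2L]
  R0 <- 0.3 * min(W, H)
  geo <- .family_geometry(config$shape_family, config$num_landmarks, R0)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  margin <- 8
  jit <- config$jitter
  lm <- NULL; A <- NULL; tv <- NULL
  for (try in seq_len(20L)) {
    sc <- 1 + runif(1L, -jit$scale, jit$scale)
    th <- runif(1L, -jit$rotate, jit$rotate) * pi / 180
    tr <- runif(2L, -jit$translate, jit$translate)
    A_ <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    t_ <- ctr + tr
    lm_ <- t(A_ %*% t(geo$loci) + t_)
    if (all(lm_[, 1L] >= margin & lm_[, 1L] <= W - 1 - margin &
            lm_[, 2L] >= margin & lm_[, 2L] <= H - 1 - margin)) {
      lm <- lm_; A <- A_; tv <- t_
      break
    }
  }
  if (is.null(lm))
    stop("could not place '", config$shape_family,
         "' inside the frame; reduce jitter or enlarge the image")
  # rasterize: canonical coords of every pixel centre via the inverse map
  Ainv <- solve(A)
  px <- rep(0:(W - 1L), times = H)
  py <- rep(0:(H - 1L), each = W)
  uv <- Ainv %*% rbind(px - tv[1L], py - tv[2L])
  inten <- geo$render(uv[1L, ], uv[2L, ])
  img <- t(matrix(0.1 + 0.85 * inten, nrow = W, ncol = H))
  img <- img + matrix(rnorm(H * W, sd = config$texture_noise_sd), H, W)
  colnames(lm) <- c("x", "y")
  landmark_sample(domain_id, img, lm, spacing(1, 1, "px"),
                  source_id = sprintf("%s-%05d", config$name, index))
}

#' Default synthetic benchmark configurations
#'
#' Three visually distinct domains with distinct landmark counts
#' (`5 / 9 / 4`), 64x64 images, and 200/20/40 train/val/test images each.
#' The `"pair2"` preset gives two domains with equal landmark counts (5/5),
#' the geometry required for full cross-anatomy parameter swaps including
#' output heads.
#'
#' @param preset `"default3"` or `"pair2"`.
#' @param seed Base seed; each domain derives its own stream from it.
#' @return List of [synth_domain_config()]s.
#' @export
synth_benchmark_configs <- function(preset = c("default3", "pair2"),
                                    seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "default3") {
    list(
      synth_domain_config("pseudo-skull", "ellipse_ring", 5L,
                          seed = seed * 131L + 1L),
      synth_domain_config("pseudo-hand", "digit_fan", 9L,
                          seed = seed * 131L + 2L),
      synth_domain_config("pseudo-chest", "twin_lobes", 4L,
                          seed = seed * 131L + 3L)
    )
  } else {
    list(
      synth_domain_config("pseudo-skull", "ellipse_ring", 5L,
                          seed = seed * 131L + 1L),
      synth_domain_config("pseudo-chest", "twin_lobes", 5L,
                          seed = seed * 131L + 3L)
    )
  }
}

#' Generate a complete synthetic benchmark
#'
#' Materializes train/val/test splits for every domain (disjoint index
#' ranges of each domain's counter-based stream) and builds the matching
#' registry with pixel spacing mode. Regeneration under the same seed is
#' bit-identical.
#'
#' @param configs List of [synth_domain_config()]s (default:
#'   [synth_benchmark_configs()] `"default3"`).
#' @param seed Base seed used when `configs` is `NULL`.
#' @return A list with `registry` (a [register_domains()] registry),
#'   `domains` (data.frame for [network_config()]), `train`, `val`, `test`
#'   (named lists of sample lists keyed by domain id), and `configs`.
#' @export
generate_benchmark <- function(configs = NULL, seed = 1L) {
  if (is.null(configs)) configs <- synth_benchmark_configs(seed = seed)
  nms <- vapply(configs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("duplicate domain names")
  specs <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    domain_spec(cf$name, cf$num_landmarks, cf$image_size, "pixel",
                n_train = cf$n_train, n_test = cf$n_test,
                domain_id = i - 1L)
  })
  registry <- register_domains(specs)
  gen_split <- function(cf, d, from, count)
    lapply(seq_len(count), function(i)
      generate_sample(cf, from + i - 1L, domain_id = d))
  train <- list(); val <- list(); test <- list()
  for (i in seq_along(configs)) {
    cf <- configs[[i]]; d <- i - 1L
    train[[as.character(d)]] <- gen_split(cf, d, 0L, cf$n_train)
    val[[as.character(d)]] <- gen_split(cf, d, cf$n_train, cf$n_val)
    test[[as.character(d)]] <- gen_split(cf, d, cf$n_train + cf$n_val,
                                         cf$n_test)
  }
  domains <- data.frame(
    domain_id = seq_along(configs) - 1L, name = nms,
    input_channels = 1L,
    num_landmarks = vapply(configs, `[[`, integer(1L), "num_landmarks")
  )
  list(registry = registry, domains = domains, train = train, val = val,
       test = test, configs = configs)
}

#' Write a benchmark to disk in the loader layout
#'
#' Writes PNG images, CSV landmark files, and a registry YAML in exactly the
#' layout [register_domains()] and [load_sample()] consume:
#' `dir/<domain>/<split>/<id>.png` + `.csv`, plus `dir/registry.yaml`.
#' Intensities are clipped to `[0, 1]` for PNG encoding.
#'
#' @param benchmark Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doms <- list()
  for (d in names(benchmark$train)) {
    spec <- benchmark$registry[[as.integer(d) + 1L]]
    for (split in c("train", "val", "test")) {
      sdir <- file.path(dir, spec$name, split)
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      for (s in benchmark[[split]][[d]]) {
        base <- file.path(sdir, s$source_id)
        png::writePNG(pmin(pmax(s$image, 0), 1), paste0(base, ".png"))
        write_landmarks(s$landmarks, paste0(base, ".csv"))
      }
    }
    doms[[length(doms) + 1L]] <- list(
      id = spec$domain_id, name = spec$name,
      num_landmarks = spec$num_landmarks,
      input_channels = spec$input_channels,
      target_size = as.list(spec$target_size),
      spacing_mode = spec$spacing_mode,
      split = list(train = unname(spec$split["n_train"]),
                   test = unname(spec$split["n_test"]))
    )
  }
  yaml::write_yaml(list(domains = doms), file.path(dir, "registry.yaml"))
  invisible(dir)
}
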