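# Shared fixtures: all built in code, nothing read from disk.

tiny_domains <- function(landmarks = c(2L, 3L)) {
  data.frame(domain_id = seq_along(landmarks) - 1L,
             input_channels = 1L,
             num_landmarks = as.integer(landmarks))
}

# smallest model that exercises every code path (32x32 inputs)
tiny_config <- function(landmarks = c(2L, 3L), variant = "gu2net",
                        seed = 42L, ...) {
  network_config(tiny_domains(landmarks),
                 encoder_widths = c(4L, 8L, 12L, 16L),
                 global_width = 6L, variant = variant, seed = seed, ...)
}

rand_image <- function(H = 32L, W = 32L, seed = 1L) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

rand_samples <- function(n, domain_id, num_landmarks, H = 32L, W = 32L,
                         seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lm <- cbind(runif(num_landmarks, 4, W - 5), runif(num_landmarks, 4, H - 5))
    landmark_sample(domain_id, matrix(runif(H * W), H, W), lm,
                    spacing(1, 1, "px"), sprintf("rand-%d", i))
  })
}

# micro synthetic benchmark for fast training contract tests
micro_benchmark <- function(landmarks = c(3L, 3L), n_train = 8L, seed = 5L) {
  fams <- c("ellipse_ring", "twin_lobes", "digit_fan", "arch_pair")
  cfgs <- lapply(seq_along(landmarks), function(i)
    synth_domain_config(paste0("micro", i), fams[i], landmarks[i],
                        jitter = list(scale = 0.05, rotate = 5,
                                      translate = 2),
                        n_train = n_train, n_val = 2L, n_test = 4L,
                        seed = seed * 17L + i))
  generate_benchmark(cfgs, seed = seed)
}

# brute-force per-pixel Gaussian heatmap (independent loop oracle)
oracle_encode <- function(landmarks, W, H, sigma, gamma = 2 * pi * sigma) {
  K <- nrow(landmarks)
  vals <- array(0, c(H, W, K))
  for (k in seq_len(K)) {
    for (yy in 0:(H - 1L)) {
      for (xx in 0:(W - 1L)) {
        d2 <- (xx - landmarks[k, 1L])^2 + (yy - landmarks[k, 2L])^2
        vals[yy + 1L, xx + 1L, k] <-
          gamma / (2 * pi * sigma) * exp(-d2 / (2 * sigma^2))
      }
    }
  }
  vals
}

# exhaustive row-major argmax (first occurrence wins)
oracle_argmax <- function(channel) {
  H <- nrow(channel); W <- ncol(channel)
  best <- -Inf; bx <- 0L; by <- 0L
  for (yy in 0:(H - 1L)) {
    for (xx in 0:(W - 1L)) {
      v <- channel[yy + 1L, xx + 1L]
      if (v > best) {
        best <- v; bx <- xx; by <- yy
      }
    }
  }
  c(bx, by)
}
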