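# The GU2Net architecture.
#
# Local branch: a U-shaped encoder-decoder whose every convolution block is a
# depth-wise separable convolution -- a domain-specific channel-wise 3x3
# convolution (one replica per registered domain, selected by domain_id at
# run time) followed by a domain-shared point-wise 1x1 convolution, each with
# its own batch normalization and leaky ReLU. Global branch: per-domain
# stack of dilated 3x3 convolutions operating at quarter resolution on the
# downsampled image and local heatmap. The two branches' sigmoid heatmaps
# are fused by element-wise multiplication.
#
# Parameters are stored in a flat named list; the name prefix ("shared." or
# "dom<i>.") *is* the shared/domain-specific partition.

#' Network configuration
#'
#' @param domains A `domain_registry` or a data.frame with columns
#'   `domain_id`, `input_channels`, `num_landmarks` (and optionally `name`).
#' @param encoder_widths Channel counts of the four encoder levels, strictly
#'   increasing. The bottleneck reuses the deepest width; the decoder mirrors
#'   the encoder with channel halving.
#' @param global_width Hidden channel count of the global dilated branch.
#'   The default, together with the default encoder widths, puts the
#'   4-domain radiograph model at about 5 million trainable parameters.
#' @param global_dilations Dilation rates of the global branch (default
#'   `c(1, 2, 5, 2, 1)`, five 3x3 convolutions per domain).
#' @param fusion_input_mode How the downsampled image and local heatmap are
#'   combined at the global branch's input: `"concat"` (channel
#'   concatenation; GU2Net-cat) or `"add"` (addition after a per-domain 1x1
#'   channel projection of the image; GU2Net-add).
#' @param variant `"gu2net"` (both branches), `"local_only"`, `"global_only"`
#'   (ablations), or `"unet_baseline"` (standard-convolution U-Net with a
#'   single shared trunk and one head covering all domains' channels).
#' @param sigma Heatmap Gaussian width in px associated with the model.
#' @param leaky_slope Negative slope of the local branch's leaky ReLU.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(domains, encoder_widths = c(64L, 128L, 256L, 512L),
                           global_width = 168L,
                           global_dilations = c(1L, 2L, 5L, 2L, 1L),
                           fusion_input_mode = c("concat", "add"),
                           variant = c("gu2net", "local_only", "global_only",
                                       "unet_baseline"),
                           sigma = 3, leaky_slope = 0.01, seed = 1L) {
  fusion_input_mode <- match.arg(fusion_input_mode)
  variant <- match.arg(variant)
  if (inherits(domains, "domain_registry")) {
    domains <- data.frame(
      domain_id = vapply(domains, `[[`, integer(1L), "domain_id"),
      name = vapply(domains, `[[`, character(1L), "name"),
      input_channels = vapply(domains, `[[`, integer(1L), "input_channels"),
      num_landmarks = vapply(domains, `[[`, integer(1L), "num_landmarks")
    )
  }
  domains <- as.data.frame(domains)
  if (is.null(domains$name)) domains$name <- paste0("domain", domains$domain_id)
  stopifnot(all(c("domain_id", "input_channels", "num_landmarks") %in%
                  names(domains)))
  domains <- domains[order(domains$domain_id), , drop = FALSE]
  if (!identical(as.integer(domains$domain_id),
                 seq_len(nrow(domains)) - 1L))
    stop("domain_ids must be contiguous from 0")
  if (length(unique(domains$input_channels)) != 1L)
    stop("all domains must share the same input channel count")
  encoder_widths <- as.integer(encoder_widths)
  if (length(encoder_widths) != 4L || any(diff(encoder_widths) <= 0))
    stop("encoder_widths must be four strictly increasing channel counts")
  if (any(global_dilations < 1L)) stop("dilations must be >= 1")
  if (leaky_slope <= 0 || leaky_slope >= 1)
    stop("leaky_slope must be in (0, 1)")
  structure(list(
    domains = domains, encoder_widths = encoder_widths,
    global_width = as.integer(global_width),
    global_dilations = as.integer(global_dilations),
    downsample_steps = 4L,
    fusion_input_mode = fusion_input_mode, variant = variant,
    sigma = sigma, leaky_slope = leaky_slope, seed = as.integer(seed)
  ), class = "network_config")
}

# ordered block table of the U-shaped trunk (shared between the separable
# local branch and the standard-convolution baseline)
.block_plan <- function(widths, cin) {
  w <- widths
  data.frame(
    name = c("enc0a", "enc0b", "enc1a", "enc1b", "enc2a", "enc2b",
             "enc3a", "enc3b", "bta", "btb", "dec3a", "dec3b",
             "dec2a", "dec2b", "dec1a", "dec1b", "dec0a", "dec0b"),
    cin = c(cin, w[1], w[1], w[2], w[2], w[3], w[3], w[4], w[4], w[4],
            2L * w[4], w[3], 2L * w[3], w[2], 2L * w[2], w[1],
            2L * w[1], w[1]),
    cout = c(w[1], w[1], w[2], w[2], w[3], w[3], w[4], w[4], w[4], w[4],
             w[3], w[3], w[2], w[2], w[1], w[1], w[1], w[1]),
    stringsAsFactors = FALSE
  )
}

# channel sequence of the global branch for one domain
.global_plan <- function(config, num_landmarks) {
  cimg <- config$domains$input_channels[1L]
  cin1 <- switch(config$variant,
    global_only = cimg,
    if (config$fusion_input_mode == "concat") cimg + num_landmarks
    else num_landmarks
  )
  g <- config$global_width
  nlay <- length(config$global_dilations)
  c(cin1, rep(g, nlay - 1L), num_landmarks)
}

#' Build a model from a configuration
#'
#' Initializes all trainable parameters (He-scaled Gaussian weights, unit
#' batch-norm scales, output-head biases at -4 so untrained heatmaps start
#' near the background probability). Initialization is deterministic given
#' the configuration and its seed.
#'
#' @param config A [network_config()].
#' @return An object of class `gu2net` holding `config`, a flat named
#'   parameter list `params`, and a state environment with batch-norm
#'   running statistics.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  p <- list()
  doms <- config$domains
  cimg <- doms$input_channels[1L]
  w <- config$encoder_widths
  plan <- .block_plan(w, cimg)
  he <- function(n, fan) rnorm(n, sd = sqrt(2 / fan))

  if (config$variant == "unet_baseline") {
    for (i in seq_len(nrow(plan))) {
      b <- plan[i, ]
      p[[paste0("shared.", b$name, ".conv.W")]] <-
        matrix(he(b$cout * 9L * b$cin, 9L * b$cin), b$cout, 9L * b$cin)
      p[[paste0("shared.", b$name, ".conv.b")]] <- numeric(b$cout)
      p[[paste0("shared.", b$name, ".bn.gamma")]] <- rep(1, b$cout)
      p[[paste0("shared.", b$name, ".bn.beta")]] <- numeric(b$cout)
    }
    ctot <- sum(doms$num_landmarks)
    p[["shared.head.W"]] <- matrix(he(ctot * w[1L], w[1L]), ctot, w[1L])
    p[["shared.head.b"]] <- rep(-4, ctot)
  } else {
    if (config$variant != "global_only") {
      for (i in seq_len(nrow(plan))) {
        b <- plan[i, ]
        for (d in doms$domain_id) {
          p[[paste0("dom", d, ".", b$name, ".dw.W")]] <-
            matrix(he(b$cin * 9L, 9L), b$cin, 9L)
          p[[paste0("dom", d, ".", b$name, ".bn1.gamma")]] <- rep(1, b$cin)
          p[[paste0("dom", d, ".", b$name, ".bn1.beta")]] <- numeric(b$cin)
        }
        p[[paste0("shared.", b$name, ".pw.W")]] <-
          matrix(he(b$cout * b$cin, b$cin), b$cout, b$cin)
        p[[paste0("shared.", b$name, ".pw.b")]] <- numeric(b$cout)
        p[[paste0("shared.", b$name, ".bn2.gamma")]] <- rep(1, b$cout)
        p[[paste0("shared.", b$name, ".bn2.beta")]] <- numeric(b$cout)
      }
      for (d in doms$domain_id) {
        ck <- doms$num_landmarks[doms$domain_id == d]
        p[[paste0("dom", d, ".head.W")]] <- matrix(he(ck * w[1L], w[1L]),
                                                   ck, w[1L])
        p[[paste0("dom", d, ".head.b")]] <- rep(-4, ck)
      }
    }
    if (config$variant != "local_only") {
      nlay <- length(config$global_dilations)
      for (d in doms$domain_id) {
        ck <- doms$num_landmarks[doms$domain_id == d]
        ch <- .global_plan(config, ck)
        if (config$variant == "gu2net" &&
            config$fusion_input_mode == "add") {
          p[[paste0("dom", d, ".gproj.W")]] <- matrix(he(ck * cimg, cimg),
                                                      ck, cimg)
          p[[paste0("dom", d, ".gproj.b")]] <- numeric(ck)
        }
        for (l in seq_len(nlay)) {
          p[[paste0("dom", d, ".glob", l, ".W")]] <-
            matrix(he(ch[l + 1L] * 9L * ch[l], 9L * ch[l]),
                   ch[l + 1L], 9L * ch[l])
          p[[paste0("dom", d, ".glob", l, ".b")]] <-
            if (l == nlay) rep(-4, ch[l + 1L]) else numeric(ch[l + 1L])
          if (l < nlay) {
            p[[paste0("dom", d, ".gbn", l, ".gamma")]] <- rep(1, ch[l + 1L])
            p[[paste0("dom", d, ".gbn", l, ".beta")]] <- numeric(ch[l + 1L])
          }
        }
      }
    }
  }
  structure(list(config = config, params = p, state = .new_state()),
            class = "gu2net")
}

#' Build the standard-convolution U-Net baseline
#'
#' A U-Net with the same trunk topology and widths but ordinary 3x3
#' convolutions, a single shared trunk (no per-domain parameters), and one
#' output head covering the union of all domains' landmark channels; only
#' the active domain's channels are supervised and decoded.
#'
#' @param config A [network_config()]; its variant is overridden.
#' @return A `gu2net` model with `variant = "unet_baseline"`.
#' @export
build_unet_baseline <- function(config) {
  config$variant <- "unet_baseline"
  build_model(config)
}

.new_state <- function() {
  e <- new.env(parent = emptyenv())
  e$bn <- list()
  e
}

.copy_model <- function(model) {
  st <- .new_state()
  st$bn <- model$state$bn
  structure(list(config = model$config, params = model$params, state = st),
            class = "gu2net")
}

#' Total trainable parameter count
#' @param model A `gu2net` model.
#' @return Integer count over all parameter tensors.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

#' @export
print.gu2net <- function(x, ...) {
  pp <- partition_params(x)
  cat(sprintf("<gu2net> variant=%s, %d domains, %.3fM parameters\n",
              x$config$variant, nrow(x$config$domains),
              pp$counts$total / 1e6))
  cat(sprintf("  shared: %d  per-domain: %s\n", pp$counts$shared,
              paste(pp$counts$per_domain, collapse = "/")))
  invisible(x)
}

#' Parameter count of a depth-wise separable convolution block
#'
#' For `t` domains, an `N`-channel input and an `M`-channel output, the
#' block holds `t` channel-wise 3x3 filters per input channel plus one
#' shared point-wise filter bank: `9*t*N + N*M` weights, versus `9*t*N*M`
#' for `t` standard 3x3 convolutions (see [count_standard_params()]).
#'
#' @param t Number of domains.
#' @param N Input channels.
#' @param M Output channels.
#' @return Integer weight count (biases and normalization excluded).
#' @examples
#' count_separable_params(4, 64, 64) # 6400
#' @export
count_separable_params <- function(t, N, M) {
  if (any(c(t, N, M) < 1)) stop("t, N, M must be positive")
  9 * t * N + N * M
}

#' @rdname count_separable_params
#' @export
count_standard_params <- function(t, N, M) {
  if (any(c(t, N, M) < 1)) stop("t, N, M must be positive")
  9 * t * N * M
}

#' Receptive field of the dilated global stack
#'
#' One pixel of the global branch's output depends on a square input window
#' of side `1 + sum(2 * dilations)` at the branch's working resolution (3x3
#' kernels, stride 1).
#'
#' @param dilations Dilation rates, default `c(1, 2, 5, 2, 1)`.
#' @return Side length of the receptive field in pixels.
#' @export
global_receptive_field <- function(dilations = c(1L, 2L, 5L, 2L, 1L)) {
  1L + sum(2L * as.integer(dilations))
}

#' Partition parameters into shared and per-domain sets
#'
#' The split is exact, disjoint, and exhaustive: every trainable tensor is
#' either domain-shared (point-wise convolutions and their normalization in
#' the local branch; everything in the U-Net baseline) or private to one
#' domain (channel-wise convolutions, their normalization, output heads,
#' and the whole global branch).
#'
#' @param model A `gu2net` model.
#' @return A `param_partition`: lists of tensor names `shared` and
#'   `per_domain` (one entry per domain id) plus raw `counts` (and
#'   `counts$total_millions`).
#' @export
partition_params <- function(model) {
  nms <- names(model$params)
  shared <- nms[startsWith(nms, "shared.")]
  domm <- regmatches(nms, regexec("^dom([0-9]+)\\.", nms))
  dom_id <- vapply(domm, function(m) if (length(m)) m[2L] else NA_character_,
                   character(1L))
  if (any(is.na(dom_id) & !startsWith(nms, "shared.")))
    stop("integrity error: parameter outside the shared/per-domain partition")
  ids <- sort(unique(as.integer(dom_id[!is.na(dom_id)])))
  per <- lapply(ids, function(i) nms[!is.na(dom_id) & as.integer(dom_id) == i])
  names(per) <- as.character(ids)
  sz <- function(x) sum(vapply(model$params[x], length, integer(1L)))
  counts <- list(shared = sz(shared),
                 per_domain = vapply(per, sz, integer(1L)),
                 total = sz(nms))
  counts$total_millions <- counts$total / 1e6
  structure(list(shared = shared, per_domain = per, counts = counts),
            class = "param_partition")
}

#' Exchange two domains' private parameters
#'
#' Swaps every per-domain tensor between domains `i` and `j`, including
#' their batch-norm running statistics; shared parameters are untouched.
#' Tensor pairs whose shapes differ (the output heads and the final global
#' convolution when the two domains have different landmark counts) are left
#' in place and reported in the `"skipped"` attribute of the result.
#'
#' @param model A `gu2net` model.
#' @param i,j Domain ids to exchange.
#' @return The model with exchanged private parameters.
#' @export
swap_domain_params <- function(model, i, j) {
  if (i == j) return(model)
  model <- .copy_model(model)
  pi_ <- paste0("dom", i, ".")
  pj_ <- paste0("dom", j, ".")
  nms <- names(model$params)
  suf_i <- sub(pi_, "", nms[startsWith(nms, pi_)], fixed = TRUE)
  suf_j <- sub(pj_, "", nms[startsWith(nms, pj_)], fixed = TRUE)
  if (!setequal(suf_i, suf_j))
    stop("domains ", i, " and ", j, " have different private parameter sets")
  skipped <- character()
  for (s in suf_i) {
    a <- model$params[[paste0(pi_, s)]]
    b <- model$params[[paste0(pj_, s)]]
    if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
      skipped <- c(skipped, s)
      next
    }
    model$params[[paste0(pi_, s)]] <- b
    model$params[[paste0(pj_, s)]] <- a
  }
  bn <- model$state$bn
  nms_bn <- names(bn) %||% character()
  keys_i <- nms_bn[startsWith(nms_bn, pi_)]
  for (k in keys_i) {
    kj <- sub(pi_, pj_, k, fixed = TRUE)
    if (!is.null(bn[[kj]]) &&
        length(bn[[k]]$mean) == length(bn[[kj]]$mean)) {
      tmp <- bn[[k]]; bn[[k]] <- bn[[kj]]; bn[[kj]] <- tmp
    }
  }
  model$state$bn <- bn
  attr(model, "skipped") <- skipped
  model
}

# ---------------------------------------------------------------------------
# forward / backward

.check_geom <- function(H, W) {
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("input spatial size must be divisible by 16, got ", W, "x", H)
}

.domain_row <- function(config, domain_id) {
  r <- which(config$domains$domain_id == domain_id)
  if (length(r) != 1L)
    stop("unknown domain_id ", domain_id,
         ": the model has no parameters for it")
  r
}

# forward pass on the internal layout. X: C x (N*H*W). Returns local,
# global, final maps (num_landmarks x N*H*W) plus caches when keep = TRUE.
.forward_net <- function(model, X, H, W, N, domain_id, training = FALSE,
                         keep = FALSE) {
  .check_geom(H, W)
  cfg <- model$config
  r <- .domain_row(cfg, domain_id)
  ck <- cfg$domains$num_landmarks[r]
  if (cfg$variant == "unet_baseline")
    return(.forward_unet(model, X, H, W, N, domain_id, training, keep))
  p <- model$params; st <- model$state
  slope <- cfg$leaky_slope
  d <- domain_id
  w <- cfg$encoder_widths
  H1 <- H / 2L; W1 <- W / 2L; H2 <- H / 4L; W2 <- W / 4L
  H3 <- H / 8L; W3 <- W / 8L; H4 <- H / 16L; W4 <- W / 16L
  cc <- list(H = H, W = W, N = N, domain_id = d)
  L <- NULL

  if (cfg$variant != "global_only") {
    sb <- function(blk, Xin, Hh, Ww)
      .sep_fwd(p, st, blk, d, Xin, Hh, Ww, N, training, slope, keep)
    e0a <- sb("enc0a", X, H, W); e0b <- sb("enc0b", e0a$y, H, W)
    mp1 <- cpp_maxpool2_fwd(e0b$y, H, W, N)
    e1a <- sb("enc1a", mp1$y, H1, W1); e1b <- sb("enc1b", e1a$y, H1, W1)
    mp2 <- cpp_maxpool2_fwd(e1b$y, H1, W1, N)
    e2a <- sb("enc2a", mp2$y, H2, W2); e2b <- sb("enc2b", e2a$y, H2, W2)
    mp3 <- cpp_maxpool2_fwd(e2b$y, H2, W2, N)
    e3a <- sb("enc3a", mp3$y, H3, W3); e3b <- sb("enc3b", e3a$y, H3, W3)
    mp4 <- cpp_maxpool2_fwd(e3b$y, H3, W3, N)
    bta <- sb("bta", mp4$y, H4, W4); btb <- sb("btb", bta$y, H4, W4)
    u3 <- cpp_resize_bilinear(btb$y, H4, W4, N, H3, W3)
    d3a <- sb("dec3a", rbind(u3, e3b$y), H3, W3)
    d3b <- sb("dec3b", d3a$y, H3, W3)
    u2 <- cpp_resize_bilinear(d3b$y, H3, W3, N, H2, W2)
    d2a <- sb("dec2a", rbind(u2, e2b$y), H2, W2)
    d2b <- sb("dec2b", d2a$y, H2, W2)
    u1 <- cpp_resize_bilinear(d2b$y, H2, W2, N, H1, W1)
    d1a <- sb("dec1a", rbind(u1, e1b$y), H1, W1)
    d1b <- sb("dec1b", d1a$y, H1, W1)
    u0 <- cpp_resize_bilinear(d1b$y, H1, W1, N, H, W)
    d0a <- sb("dec0a", rbind(u0, e0b$y), H, W)
    d0b <- sb("dec0b", d0a$y, H, W)
    zh <- p[[paste0("dom", d, ".head.W")]] %*% d0b$y +
      p[[paste0("dom", d, ".head.b")]]
    L <- .sigmoid(zh)
    if (keep) {
      cc$blocks <- list(e0a = e0a$cache, e0b = e0b$cache, e1a = e1a$cache,
                        e1b = e1b$cache, e2a = e2a$cache, e2b = e2b$cache,
                        e3a = e3a$cache, e3b = e3b$cache, bta = bta$cache,
                        btb = btb$cache, d3a = d3a$cache, d3b = d3b$cache,
                        d2a = d2a$cache, d2b = d2b$cache, d1a = d1a$cache,
                        d1b = d1b$cache, d0a = d0a$cache, d0b = d0b$cache)
      cc$pool_idx <- list(mp1$idx, mp2$idx, mp3$idx, mp4$idx)
      cc$d0b_y <- d0b$y
      cc$L <- L
    }
  }

  if (cfg$variant == "local_only") {
    G <- matrix(1, ck, ncol(X))
    Fm <- L
  } else {
    H4g <- H / 4L; W4g <- W / 4L
    img4 <- cpp_resize_bilinear(X, H, W, N, H4g, W4g)
    if (cfg$variant == "global_only") {
      G0 <- img4
    } else {
      L4 <- cpp_resize_bilinear(L, H, W, N, H4g, W4g)
      if (cfg$fusion_input_mode == "concat") {
        G0 <- rbind(img4, L4)
      } else {
        zp <- p[[paste0("dom", d, ".gproj.W")]] %*% img4 +
          p[[paste0("dom", d, ".gproj.b")]]
        G0 <- zp + L4
      }
    }
    nlay <- length(cfg$global_dilations)
    gin <- G0
    gcc <- vector("list", nlay)
    sg <- NULL
    for (l in seq_len(nlay)) {
      dil <- cfg$global_dilations[l]
      cols <- cpp_im2col3(gin, H4g, W4g, N, dil)
      z <- p[[paste0("dom", d, ".glob", l, ".W")]] %*% cols +
        p[[paste0("dom", d, ".glob", l, ".b")]]
      if (l < nlay) {
        bn <- .bn_fwd(p, st, paste0("dom", d, ".gbn", l), z, training)
        h <- cpp_lrelu_fwd(bn$y, 0)       # plain ReLU in the global branch
        if (keep) gcc[[l]] <- list(cols = cols, cin = nrow(gin),
                                   bn = bn$cache, y = h, dil = dil)
        gin <- h
      } else {
        sg <- .sigmoid(z)
        if (keep) gcc[[l]] <- list(cols = cols, cin = nrow(gin), dil = dil)
      }
    }
    G <- cpp_resize_bilinear(sg, H4g, W4g, N, H, W)
    Fm <- if (cfg$variant == "global_only") G else L * G
    if (is.null(L)) L <- matrix(1, ck, ncol(G))
    if (keep) {
      cc$glayers <- gcc
      cc$img4 <- img4
      cc$sg <- sg
      cc$G <- G
      cc$H4g <- H4g; cc$W4g <- W4g
    }
  }
  list(local = L, global = G, final = Fm, cache = if (keep) cc)
}

.forward_unet <- function(model, X, H, W, N, domain_id, training, keep) {
  p <- model$params; st <- model$state
  cfg <- model$config
  slope <- cfg$leaky_slope
  H1 <- H / 2L; W1 <- W / 2L; H2 <- H / 4L; W2 <- W / 4L
  H3 <- H / 8L; W3 <- W / 8L; H4 <- H / 16L; W4 <- W / 16L
  sb <- function(blk, Xin, Hh, Ww)
    .std_fwd(p, st, blk, Xin, Hh, Ww, N, training, slope, keep)
  e0a <- sb("enc0a", X, H, W); e0b <- sb("enc0b", e0a$y, H, W)
  mp1 <- cpp_maxpool2_fwd(e0b$y, H, W, N)
  e1a <- sb("enc1a", mp1$y, H1, W1); e1b <- sb("enc1b", e1a$y, H1, W1)
  mp2 <- cpp_maxpool2_fwd(e1b$y, H1, W1, N)
  e2a <- sb("enc2a", mp2$y, H2, W2); e2b <- sb("enc2b", e2a$y, H2, W2)
  mp3 <- cpp_maxpool2_fwd(e2b$y, H2, W2, N)
  e3a <- sb("enc3a", mp3$y, H3, W3); e3b <- sb("enc3b", e3a$y, H3, W3)
  mp4 <- cpp_maxpool2_fwd(e3b$y, H3, W3, N)
  bta <- sb("bta", mp4$y, H4, W4); btb <- sb("btb", bta$y, H4, W4)
  u3 <- cpp_resize_bilinear(btb$y, H4, W4, N, H3, W3)
  d3a <- sb("dec3a", rbind(u3, e3b$y), H3, W3); d3b <- sb("dec3b", d3a$y, H3, W3)
  u2 <- cpp_resize_bilinear(d3b$y, H3, W3, N, H2, W2)
  d2a <- sb("dec2a", rbind(u2, e2b$y), H2, W2); d2b <- sb("dec2b", d2a$y, H2, W2)
  u1 <- cpp_resize_bilinear(d2b$y, H2, W2, N, H1, W1)
  d1a <- sb("dec1a", rbind(u1, e1b$y), H1, W1); d1b <- sb("dec1b", d1a$y, H1, W1)
  u0 <- cpp_resize_bilinear(d1b$y, H1, W1, N, H, W)
  d0a <- sb("dec0a", rbind(u0, e0b$y), H, W); d0b <- sb("dec0b", d0a$y, H, W)
  rows <- .head_rows(cfg, domain_id)
  zh <- p[["shared.head.W"]][rows, , drop = FALSE] %*% d0b$y +
    p[["shared.head.b"]][rows]
  Fm <- .sigmoid(zh)
  cc <- NULL
  if (keep) {
    cc <- list(H = H, W = W, N = N, domain_id = domain_id,
               blocks = list(e0a = e0a$cache, e0b = e0b$cache,
                             e1a = e1a$cache, e1b = e1b$cache,
                             e2a = e2a$cache, e2b = e2b$cache,
                             e3a = e3a$cache, e3b = e3b$cache,
                             bta = bta$cache, btb = btb$cache,
                             d3a = d3a$cache, d3b = d3b$cache,
                             d2a = d2a$cache, d2b = d2b$cache,
                             d1a = d1a$cache, d1b = d1b$cache,
                             d0a = d0a$cache, d0b = d0b$cache),
               pool_idx = list(mp1$idx, mp2$idx, mp3$idx, mp4$idx),
               d0b_y = d0b$y, L = Fm)
  }
  list(local = Fm, global = matrix(1, nrow(Fm), ncol(Fm)), final = Fm,
       cache = cc)
}

.head_rows <- function(config, domain_id) {
  nl <- config$domains$num_landmarks
  r <- .domain_row(config, domain_id)
  off <- if (r > 1L) sum(nl[seq_len(r - 1L)]) else 0L
  off + seq_len(nl[r])
}

# backward pass from the gradient of the loss w.r.t. the final fused map.
# Returns the named gradient list (shared + active domain only).
.backward_net <- function(model, out, dF) {
  cfg <- model$config
  cc <- out$cache
  if (is.null(cc)) stop("forward pass was run without keep = TRUE")
  if (cfg$variant == "unet_baseline")
    return(.backward_unet(model, out, dF))
  p <- model$params
  slope <- cfg$leaky_slope
  d <- cc$domain_id
  H <- cc$H; W <- cc$W; N <- cc$N
  w <- cfg$encoder_widths
  gacc <- .gnew()

  if (cfg$variant == "local_only") {
    dL <- dF; dG <- NULL
  } else if (cfg$variant == "global_only") {
    dG <- dF; dL <- NULL
  } else {
    dL <- dF * cc$G
    dG <- dF * cc$L
  }

  if (!is.null(dG)) {
    H4g <- cc$H4g; W4g <- cc$W4g
    dsg <- cpp_resize_bilinear_adj(dG, H4g, W4g, N, H, W)
    dz <- dsg * cc$sg * (1 - cc$sg)
    nlay <- length(cfg$global_dilations)
    dprev <- NULL
    for (l in rev(seq_len(nlay))) {
      lc <- cc$glayers[[l]]
      Wl <- p[[paste0("dom", d, ".glob", l, ".W")]]
      .gadd(gacc, paste0("dom", d, ".glob", l, ".W"), tcrossprod(dz, lc$cols))
      .gadd(gacc, paste0("dom", d, ".glob", l, ".b"), rowSums(dz))
      dcols <- crossprod(Wl, dz)
      dprev <- cpp_col2im3(dcols, lc$cin, H4g, W4g, N, lc$dil)
      if (l > 1L) {
        lp <- cc$glayers[[l - 1L]]
        dh <- cpp_lrelu_bwd(dprev, lp$y, 0)
        bb <- .bn_bwd(dh, lp$bn)
        .gadd(gacc, paste0("dom", d, ".gbn", l - 1L, ".gamma"), bb$dgamma)
        .gadd(gacc, paste0("dom", d, ".gbn", l - 1L, ".beta"), bb$dbeta)
        dz <- bb$dX
      }
    }
    if (cfg$variant == "gu2net") {
      cimg <- cfg$domains$input_channels[1L]
      ck <- nrow(dF)
      if (cfg$fusion_input_mode == "concat") {
        dL4 <- dprev[cimg + seq_len(ck), , drop = FALSE]
      } else {
        dL4 <- dprev
        .gadd(gacc, paste0("dom", d, ".gproj.W"), tcrossprod(dprev, cc$img4))
        .gadd(gacc, paste0("dom", d, ".gproj.b"), rowSums(dprev))
      }
      dL <- dL + cpp_resize_bilinear_adj(dL4, H, W, N, H4g, W4g)
    }
  }

  if (cfg$variant != "global_only") {
    dzh <- dL * cc$L * (1 - cc$L)
    .gadd(gacc, paste0("dom", d, ".head.W"), tcrossprod(dzh, cc$d0b_y))
    .gadd(gacc, paste0("dom", d, ".head.b"), rowSums(dzh))
    g <- crossprod(p[[paste0("dom", d, ".head.W")]], dzh)
    bk <- cc$blocks
    H1 <- H / 2L; W1 <- W / 2L; H2 <- H / 4L; W2 <- W / 4L
    H3 <- H / 8L; W3 <- W / 8L; H4 <- H / 16L; W4 <- W / 16L
    g <- .sep_bwd(p, g, bk$d0b, gacc, slope)
    g <- .sep_bwd(p, g, bk$d0a, gacc, slope)
    du0 <- g[seq_len(w[1L]), , drop = FALSE]
    de0s <- g[w[1L] + seq_len(w[1L]), , drop = FALSE]
    g <- cpp_resize_bilinear_adj(du0, H1, W1, N, H, W)
    g <- .sep_bwd(p, g, bk$d1b, gacc, slope)
    g <- .sep_bwd(p, g, bk$d1a, gacc, slope)
    du1 <- g[seq_len(w[2L]), , drop = FALSE]
    de1s <- g[w[2L] + seq_len(w[2L]), , drop = FALSE]
    g <- cpp_resize_bilinear_adj(du1, H2, W2, N, H1, W1)
    g <- .sep_bwd(p, g, bk$d2b, gacc, slope)
    g <- .sep_bwd(p, g, bk$d2a, gacc, slope)
    du2 <- g[seq_len(w[3L]), , drop = FALSE]
    de2s <- g[w[3L] + seq_len(w[3L]), , drop = FALSE]
    g <- cpp_resize_bilinear_adj(du2, H3, W3, N, H2, W2)
    g <- .sep_bwd(p, g, bk$d3b, gacc, slope)
    g <- .sep_bwd(p, g, bk$d3a, gacc, slope)
    du3 <- g[seq_len(w[4L]), , drop = FALSE]
    de3s <- g[w[4L] + seq_len(w[4L]), , drop = FALSE]
    g <- cpp_resize_bilinear_adj(du3, H4, W4, N, H3, W3)
    g <- .sep_bwd(p, g, bk$btb, gacc, slope)
    g <- .sep_bwd(p, g, bk$bta, gacc, slope)
    de3 <- de3s + cpp_maxpool2_bwd(g, cc$pool_idx[[4L]], N * H3 * W3)
    g <- .sep_bwd(p, de3, bk$e3b, gacc, slope)
    g <- .sep_bwd(p, g, bk$e3a, gacc, slope)
    de2 <- de2s + cpp_maxpool2_bwd(g, cc$pool_idx[[3L]], N * H2 * W2)
    g <- .sep_bwd(p, de2, bk$e2b, gacc, slope)
    g <- .sep_bwd(p, g, bk$e2a, gacc, slope)
    de1 <- de1s + cpp_maxpool2_bwd(g, cc$pool_idx[[2L]], N * H1 * W1)
    g <- .sep_bwd(p, de1, bk$e1b, gacc, slope)
    g <- .sep_bwd(p, g, bk$e1a, gacc, slope)
    de0 <- de0s + cpp_maxpool2_bwd(g, cc$pool_idx[[1L]], N * H * W)
    g <- .sep_bwd(p, de0, bk$e0b, gacc, slope)
    .sep_bwd(p, g, bk$e0a, gacc, slope)
  }
  .gas_list(gacc)
}

.backward_unet <- function(model, out, dF) {
  cfg <- model$config
  cc <- out$cache
  p <- model$params
  slope <- cfg$leaky_slope
  H <- cc$H; W <- cc$W; N <- cc$N
  w <- cfg$encoder_widths
  gacc <- .gnew()
  Fm <- cc$L
  dzh <- dF * Fm * (1 - Fm)
  rows <- .head_rows(cfg, cc$domain_id)
  Whead <- p[["shared.head.W"]]
  dWh <- matrix(0, nrow(Whead), ncol(Whead))
  dWh[rows, ] <- tcrossprod(dzh, cc$d0b_y)
  dbh <- numeric(nrow(Whead))
  dbh[rows] <- rowSums(dzh)
  .gadd(gacc, "shared.head.W", dWh)
  .gadd(gacc, "shared.head.b", dbh)
  g <- crossprod(Whead[rows, , drop = FALSE], dzh)
  bk <- cc$blocks
  H1 <- H / 2L; W1 <- W / 2L; H2 <- H / 4L; W2 <- W / 4L
  H3 <- H / 8L; W3 <- W / 8L; H4 <- H / 16L; W4 <- W / 16L
  g <- .std_bwd(p, g, bk$d0b, gacc, slope)
  g <- .std_bwd(p, g, bk$d0a, gacc, slope)
  du0 <- g[seq_len(w[1L]), , drop = FALSE]
  de0s <- g[w[1L] + seq_len(w[1L]), , drop = FALSE]
  g <- cpp_resize_bilinear_adj(du0, H1, W1, N, H, W)
  g <- .std_bwd(p, g, bk$d1b, gacc, slope)
  g <- .std_bwd(p, g, bk$d1a, gacc, slope)
  du1 <- g[seq_len(w[2L]), , drop = FALSE]
  de1s <- g[w[2L] + seq_len(w[2L]), , drop = FALSE]
  g <- cpp_resize_bilinear_adj(du1, H2, W2, N, H1, W1)
  g <- .std_bwd(p, g, bk$d2b, gacc, slope)
  g <- .std_bwd(p, g, bk$d2a, gacc, slope)
  du2 <- g[seq_len(w[3L]), , drop = FALSE]
  de2s <- g[w[3L] + seq_len(w[3L]), , drop = FALSE]
  g <- cpp_resize_bilinear_adj(du2, H3, W3, N, H2, W2)
  g <- .std_bwd(p, g, bk$d3b, gacc, slope)
  g <- .std_bwd(p, g, bk$d3a, gacc, slope)
  du3 <- g[seq_len(w[4L]), , drop = FALSE]
  de3s <- g[w[4L] + seq_len(w[4L]), , drop = FALSE]
  g <- cpp_resize_bilinear_adj(du3, H4, W4, N, H3, W3)
  g <- .std_bwd(p, g, bk$btb, gacc, slope)
  g <- .std_bwd(p, g, bk$bta, gacc, slope)
  de3 <- de3s + cpp_maxpool2_bwd(g, cc$pool_idx[[4L]], N * H3 * W3)
  g <- .std_bwd(p, de3, bk$e3b, gacc, slope)
  g <- .std_bwd(p, g, bk$e3a, gacc, slope)
  de2 <- de2s + cpp_maxpool2_bwd(g, cc$pool_idx[[3L]], N * H2 * W2)
  g <- .std_bwd(p, de2, bk$e2b, gacc, slope)
  g <- .std_bwd(p, g, bk$e2a, gacc, slope)
  de1 <- de1s + cpp_maxpool2_bwd(g, cc$pool_idx[[2L]], N * H1 * W1)
  g <- .std_bwd(p, de1, bk$e1b, gacc, slope)
  g <- .std_bwd(p, g, bk$e1a, gacc, slope)
  de0 <- de0s + cpp_maxpool2_bwd(g, cc$pool_idx[[1L]], N * H * W)
  g <- .std_bwd(p, de0, bk$e0b, gacc, slope)
  .std_bwd(p, g, bk$e0a, gacc, slope)
  .gas_list(gacc)
}

# ---------------------------------------------------------------------------
# user-facing inference

# image list -> internal batch matrix (1-channel images)
.images_to_batch <- function(images) {
  do.call(cbind, lapply(images, .image_to_mat))
}

.map_to_stack <- function(M, H, W, n, sigma, role) {
  K <- nrow(M)
  vals <- array(0, c(H, W, K))
  sidx <- (n - 1L) * H * W + seq_len(H * W)
  for (k in seq_len(K))
    vals[, , k] <- t(matrix(M[k, sidx], nrow = W, ncol = H))
  heatmap_stack(pmin(pmax(vals, 0), 1), sigma = sigma, role = role)
}

#' Run the network on one image
#'
#' Z-score-normalizes the image, runs the forward pass for the given
#' domain, and returns the local, global, and final (fused) heatmap stacks
#' for inspection. The final stack is the element-wise product of the two
#' branches (for the ablation variants it equals the active branch).
#'
#' @param model A `gu2net` model.
#' @param image Numeric `height x width` intensity matrix; spatial dims must
#'   be divisible by 16.
#' @param domain_id Registered 0-based domain id.
#' @param normalize Apply [zscore_normalize()] first (default `TRUE`).
#' @return A list of three [heatmap_stack()]s: `local`, `global`, `final`.
#' @export
predict_heatmaps <- function(model, image, domain_id, normalize = TRUE) {
  if (normalize) image <- zscore_normalize(image)
  H <- nrow(image); W <- ncol(image)
  out <- .forward_net(model, .image_to_mat(image), H, W, 1L, domain_id)
  sig <- model$config$sigma
  list(local = .map_to_stack(out$local, H, W, 1L, sig, "local"),
       global = .map_to_stack(out$global, H, W, 1L, sig, "global"),
       final = .map_to_stack(out$final, H, W, 1L, sig, "final"))
}

#' Predict landmark coordinates for one image
#'
#' Forward pass plus argmax decoding of the final heatmap.
#'
#' @inheritParams predict_heatmaps
#' @return Numeric `num_landmarks x 2` matrix of 0-based (x, y) coordinates.
#' @export
predict_landmarks <- function(model, image, domain_id, normalize = TRUE) {
  decode_landmarks(predict_heatmaps(model, image, domain_id,
                                    normalize = normalize)$final)
}
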