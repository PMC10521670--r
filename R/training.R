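# Loss, augmentation, mixed-domain batch sampling, Adam with a cyclic
# learning-rate schedule, and checkpoint selection by minimum pooled
# validation loss.

#' Augmentation configuration
#'
#' On-the-fly rigid augmentation: with probability `rotate_prob` the image is
#' rotated about its centre by an angle drawn uniformly in
#' `[-rotate_deg, rotate_deg]`; independently, with probability
#' `translate_prob` it is translated by integer offsets drawn uniformly in
#' `[-translate_px, translate_px]` per axis.
#'
#' @param rotate_deg Maximum rotation in degrees (default 2).
#' @param rotate_prob Rotation probability (default 0.1).
#' @param translate_px Maximum translation per axis in px (default 10).
#' @param translate_prob Translation probability (default 0.1).
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotate_deg = 2, rotate_prob = 0.1,
                           translate_px = 10L, translate_prob = 0.1) {
  stopifnot(rotate_prob >= 0, rotate_prob <= 1,
            translate_prob >= 0, translate_prob <= 1)
  structure(list(rotate_deg = rotate_deg, rotate_prob = rotate_prob,
                 translate_px = as.integer(translate_px),
                 translate_prob = translate_prob),
            class = "augment_config")
}

#' Training configuration
#'
#' Defaults follow the training recipe the model is designed for: batches of
#' 4, Adam, a cyclic learning-rate schedule decaying from `lr_max` to
#' `lr_min` over up to 100 epochs, Gaussian targets with `sigma = 3` px, and
#' selection of the checkpoint with minimum pooled validation loss.
#'
#' @param batch_size Images per optimization step (default 4).
#' @param epochs Training epochs (default 100).
#' @param lr_max,lr_min Learning-rate range (defaults 1e-2 and 1e-4).
#' @param sigma Heatmap Gaussian width in px (default 3).
#' @param seed RNG seed governing batching, augmentation and splits.
#' @param augmentation An [augment_config()].
#' @param cycle_epochs Length of one learning-rate cycle in epochs: within a
#'   cycle the rate decays linearly from the cycle's peak to `lr_min`, and
#'   peaks decay geometrically across cycles from `lr_max` towards `lr_min`.
#' @param val_fraction Fraction of each training split held out for
#'   validation when no validation sets are passed (default 0.1).
#' @param clip_norm Global gradient-norm clip (default 5; `Inf` disables).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 4L, epochs = 100L, lr_max = 1e-2,
                         lr_min = 1e-4, sigma = 3, seed = 1L,
                         augmentation = augment_config(),
                         cycle_epochs = 10L, val_fraction = 0.1,
                         clip_norm = 5) {
  if (lr_min >= lr_max) stop("lr_min must be below lr_max")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_max = lr_max,
                 lr_min = lr_min, sigma = sigma, seed = as.integer(seed),
                 augmentation = augmentation,
                 cycle_epochs = as.integer(cycle_epochs),
                 val_fraction = val_fraction, clip_norm = clip_norm),
            class = "train_config")
}

#' Soft-label binary cross-entropy between heatmaps
#'
#' `sum(-y*log(f) - (1-y)*log(1-f))` over all pixels and channels, summed
#' within an image and averaged across the batch. Predictions are clamped to
#' `[eps, 1-eps]` before the logs.
#'
#' @param prediction,target [heatmap_stack()]s or numeric arrays/matrices of
#'   identical shape; the target holds soft labels in `[0, 1]`.
#' @param n_batch Number of images the tensors cover (for bare matrices in
#'   the internal channel-row layout; stacks are single-image).
#' @param eps Clamp width (default 1e-6).
#' @return Non-negative scalar loss.
#' @examples
#' heatmap_bce_loss(matrix(0.5), matrix(0.5)) # log(2)
#' @export
heatmap_bce_loss <- function(prediction, target, n_batch = 1L, eps = 1e-6) {
  f <- if (inherits(prediction, "heatmap_stack")) prediction$values else prediction
  y <- if (inherits(target, "heatmap_stack")) target$values else target
  if (!identical(dim(f), dim(y)))
    stop("prediction and target shapes differ")
  if (any(!is.finite(f)) || any(!is.finite(y)))
    stop("non-finite values in loss inputs")
  if (is.matrix(f) && is.matrix(y)) return(cpp_bce_sum(f, y, eps) / n_batch)
  f <- pmin(pmax(f, eps), 1 - eps)
  sum(-y * log(f) - (1 - y) * log(1 - f)) / n_batch
}

# gradient of the batch-mean BCE w.r.t. the (unclamped) prediction
.bce_grad <- function(f, y, n_batch, eps = 1e-6) {
  cpp_bce_grad(f, y, n_batch, eps)
}

#' Rigid augmentation of one sample
#'
#' Applies the draw described in [augment_config()] using R's RNG. Landmark
#' coordinates are transformed by the same rigid map as the image; if any
#' landmark would leave the frame the transform is redrawn (bounded
#' retries), falling back to the identity. When a `target_stack` is given it
#' is re-encoded from the transformed landmarks (not warped).
#'
#' @param sample A [landmark_sample()].
#' @param config An [augment_config()].
#' @param target_stack Optional [heatmap_stack()] target to re-encode.
#' @param max_retries Redraw attempts before falling back to identity.
#' @return The augmented sample, or `list(sample, target_stack)` when a
#'   target was supplied.
#' @export
augment_sample <- function(sample, config = augment_config(),
                           target_stack = NULL, max_retries = 10L) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  out <- sample
  for (try in seq_len(max_retries)) {
    theta <- if (runif(1L) < config$rotate_prob)
      runif(1L, -config$rotate_deg, config$rotate_deg) * pi / 180 else 0
    tr <- if (runif(1L) < config$translate_prob)
      c(sample.int(2L * config$translate_px + 1L, 1L),
        sample.int(2L * config$translate_px + 1L, 1L)) -
        config$translate_px - 1L else c(0L, 0L)
    if (theta == 0 && all(tr == 0L)) break
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
    lm <- t(R %*% (t(sample$landmarks) - ctr) + ctr + tr)
    if (any(lm[, 1L] < 0 | lm[, 1L] > W - 1 |
            lm[, 2L] < 0 | lm[, 2L] > H - 1)) next
    Minv <- t(R)                       # R^-1 for a rotation
    v <- ctr - Minv %*% (ctr + tr)
    img <- cpp_affine_sample(sample$image, Minv[1L, 1L], Minv[1L, 2L],
                             Minv[2L, 1L], Minv[2L, 2L], v[1L], v[2L])
    out <- landmark_sample(sample$domain_id, img, lm, sample$spacing,
                           sample$source_id)
    break
  }
  if (is.null(target_stack)) return(out)
  ts <- encode_heatmaps(out$landmarks, c(W, H), sigma = target_stack$sigma,
                        gamma = target_stack$gamma, role = "target")
  list(sample = out, target_stack = ts)
}

#' Mixed-domain batch schedule for one epoch
#'
#' Every emitted batch is homogeneous in domain; the domain of each batch is
#' drawn with probability proportional to that domain's training-set size,
#' and within a domain images are taken from a shuffled queue that reshuffles
#' when exhausted, so each image is visited about once per epoch in
#' expectation. One epoch holds `floor(total images / batch_size)` batches.
#'
#' @param datasets List of training sets (each a list of
#'   [landmark_sample()]s of one domain).
#' @param batch_size Images per batch.
#' @return List of batches, each `list(dataset, domain_id, indices)` where
#'   `dataset` indexes into `datasets`.
#' @export
sample_batches <- function(datasets, batch_size = 4L) {
  if (length(datasets) == 0L) stop("empty dataset list")
  sizes <- vapply(datasets, length, integer(1L))
  if (any(sizes == 0L)) stop("empty dataset in list")
  doms <- vapply(datasets, function(ds) ds[[1L]]$domain_id, integer(1L))
  nb <- max(1L, sum(sizes) %/% batch_size)
  draw <- sample.int(length(datasets), nb, replace = TRUE, prob = sizes)
  queues <- lapply(sizes, sample.int)
  heads <- rep(1L, length(datasets))
  batches <- vector("list", nb)
  for (b in seq_len(nb)) {
    ds <- draw[b]
    idx <- integer(batch_size)
    for (k in seq_len(batch_size)) {
      if (heads[ds] > sizes[ds]) {
        queues[[ds]] <- sample.int(sizes[ds])
        heads[ds] <- 1L
      }
      idx[k] <- queues[[ds]][heads[ds]]
      heads[ds] <- heads[ds] + 1L
    }
    batches[[b]] <- list(dataset = ds, domain_id = doms[ds], indices = idx)
  }
  batches
}

#' Cyclic learning-rate trace
#'
#' Per-step learning rates for a whole run: cycles of `cycle_epochs` within
#' which the rate decays linearly from the cycle peak to `lr_min`; peaks
#' decay geometrically from `lr_max` so the trace starts at `lr_max` and
#' ends at `lr_min`.
#'
#' @param config A [train_config()].
#' @param steps_per_epoch Optimization steps per epoch.
#' @return Numeric vector of length `epochs * steps_per_epoch`.
#' @export
lr_schedule <- function(config, steps_per_epoch) {
  total <- config$epochs * steps_per_epoch
  clen <- min(total, max(1L, config$cycle_epochs * steps_per_epoch))
  ncyc <- ceiling(total / clen)
  s <- seq_len(total) - 1L
  cyc <- s %/% clen
  pos <- pmin(1, (s %% clen) / max(1L, clen - 1L))
  peak <- config$lr_max * (config$lr_min / config$lr_max)^(cyc / ncyc)
  config$lr_min + (peak - config$lr_min) * (1 - pos)
}

# --------------------------------------------------------------------------
# Adam

.adam_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- list()
  e
}

.adam_step <- function(params, grads, opt, lr, clip = Inf,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn2 <- sum(vapply(grads, function(g) sum(g * g), numeric(1L)))
  if (is.finite(clip) && gn2 > clip^2) {
    sc <- clip / sqrt(gn2)
    grads <- lapply(grads, function(g) g * sc)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    t <- (opt$t[[nm]] %||% 0L) + 1L
    m <- if (is.null(opt$m[[nm]])) (1 - beta1) * g
         else beta1 * opt$m[[nm]] + (1 - beta1) * g
    v <- if (is.null(opt$v[[nm]])) (1 - beta2) * g * g
         else beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    opt$t[[nm]] <- t; opt$m[[nm]] <- m; opt$v[[nm]] <- v
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

# --------------------------------------------------------------------------
# training loop

# landmarks of a sample -> target map in channel-row layout (K x H*W)
.encode_map <- function(landmarks, W, H, sigma) {
  st <- encode_heatmaps(landmarks, c(W, H), sigma = sigma)
  K <- nrow(landmarks)
  m <- matrix(0, K, H * W)
  for (k in seq_len(K)) m[k, ] <- as.vector(t(st$values[, , k]))
  m
}

.batch_tensors <- function(samples, sigma, augment_cfg = NULL) {
  n <- length(samples)
  Xs <- vector("list", n); Ts <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    if (!is.null(augment_cfg)) s <- augment_sample(s, augment_cfg)
    Xs[[i]] <- .image_to_mat(zscore_normalize(s$image))
    Ts[[i]] <- .encode_map(s$landmarks, ncol(s$image), nrow(s$image), sigma)
  }
  list(X = do.call(cbind, Xs), T = do.call(cbind, Ts), n = n)
}

# mean per-image validation loss of one domain's set (no augmentation)
.val_loss <- function(model, samples, sigma, batch_size = 8L) {
  n <- length(samples)
  tot <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    bt <- .batch_tensors(samples[i:j], sigma)
    H <- nrow(samples[[i]]$image); W <- ncol(samples[[i]]$image)
    out <- .forward_net(model, bt$X, H, W, bt$n,
                        samples[[i]]$domain_id, training = FALSE)
    tot <- tot + heatmap_bce_loss(out$final, bt$T, n_batch = 1L)
    i <- j + 1L
  }
  tot / n
}

#' Train a model
#'
#' Optimizes the soft-label BCE between the final fused heatmap and the
#' Gaussian target with Adam under the cyclic learning-rate schedule of
#' [lr_schedule()], drawing mixed-domain batches via [sample_batches()] and
#' augmenting on the fly. After every epoch the validation loss is computed
#' per domain without augmentation; the returned checkpoint is the epoch
#' with minimum pooled (sample-weighted) validation loss. A non-finite
#' training loss aborts the run, returning the last finite state.
#'
#' @param model A `gu2net` model (any variant).
#' @param train_sets List of training sets, one per domain (lists of
#'   [landmark_sample()]s; images must share the model's input geometry).
#' @param val_sets Optional validation sets in the same layout; if `NULL`,
#'   `val_fraction` of each training set is held out deterministically.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list of class `train_result`: `model` (best checkpoint),
#'   `last_model`, and `history` (a data.frame of per-epoch train loss,
#'   per-domain and pooled validation losses, with the per-step
#'   learning-rate trace as attribute `lr_trace` and the best epoch in
#'   attribute `best_epoch`).
#' @export
train_model <- function(model, train_sets, val_sets = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "gu2net"), inherits(config, "train_config"))
  set.seed(config$seed)
  if (is.null(val_sets)) {
    val_sets <- list()
    for (i in seq_along(train_sets)) {
      n <- length(train_sets[[i]])
      nv <- max(1L, round(config$val_fraction * n))
      hold <- sample.int(n, nv)
      val_sets[[i]] <- train_sets[[i]][hold]
      train_sets[[i]] <- train_sets[[i]][-hold]
    }
  }
  spe <- max(1L, sum(vapply(train_sets, length, integer(1L))) %/%
               config$batch_size)
  lrs <- lr_schedule(config, spe)
  opt <- .adam_new()
  dom_names <- paste0("val_", vapply(seq_along(val_sets), function(i)
    as.character(val_sets[[i]][[1L]]$domain_id), character(1L)))
  nval <- vapply(val_sets, length, numeric(1L))
  hist_rows <- vector("list", config$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL, bn = NULL)
  step <- 0L
  aborted <- FALSE
  for (ep in seq_len(config$epochs)) {
    sched <- sample_batches(train_sets, config$batch_size)
    ep_loss <- 0
    for (b in sched) {
      step <- step + 1L
      samples <- train_sets[[b$dataset]][b$indices]
      bt <- .batch_tensors(samples, config$sigma, config$augmentation)
      H <- nrow(samples[[1L]]$image); W <- ncol(samples[[1L]]$image)
      out <- .forward_net(model, bt$X, H, W, bt$n, b$domain_id,
                          training = TRUE, keep = TRUE)
      loss <- heatmap_bce_loss(out$final, bt$T, n_batch = bt$n)
      if (!is.finite(loss)) {
        warning("non-finite training loss at epoch ", ep,
                "; aborting with the last finite state")
        aborted <- TRUE
        break
      }
      ep_loss <- ep_loss + loss
      dF <- .bce_grad(out$final, bt$T, bt$n)
      grads <- .backward_net(model, out, dF)
      model$params <- .adam_step(model$params, grads, opt, lrs[step],
                                 config$clip_norm)
    }
    if (aborted) break
    vl <- vapply(val_sets, function(vs)
      .val_loss(model, vs, config$sigma), numeric(1L))
    pooled <- sum(vl * nval) / sum(nval)
    hist_rows[[ep]] <- c(epoch = ep, train_loss = ep_loss / length(sched),
                         setNames(vl, dom_names), val_pooled = pooled)
    if (pooled < best$loss) {
      best$loss <- pooled
      best$epoch <- ep
      best$params <- model$params
      best$bn <- model$state$bn
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4g  val %.4g  lr %.3g",
                      ep, ep_loss / length(sched), pooled, lrs[step]))
  }
  history <- as.data.frame(do.call(rbind, hist_rows[!vapply(hist_rows,
                                                            is.null,
                                                            logical(1L))]))
  attr(history, "lr_trace") <- lrs[seq_len(step)]
  attr(history, "best_epoch") <- best$epoch
  best_model <- .copy_model(model)
  if (!is.null(best$params)) {
    best_model$params <- best$params
    best_model$state$bn <- best$bn
  }
  structure(list(model = best_model, last_model = model, history = history,
                 best_epoch = best$epoch, config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("<train_result> %d epochs, best epoch %s (val %.5g)\n",
              nrow(h), x$best_epoch,
              if (nrow(h)) min(h$val_pooled) else NA))
  invisible(x)
}
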