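# Radial-error metrics (MRE/SDR) and the cross-anatomy / domain-count
# experiment harnesses.

#' Radial errors between predicted and true landmarks
#'
#' Per landmark, `||(dx*sx, dy*sy)||` with the coordinate differences in
#' pixels and the spacing applied per axis before the norm (so anisotropic
#' spacing after resizing is handled exactly). Pixel-mode domains use unit
#' spacing and report in px.
#'
#' @param predicted,truth Numeric `n x 2` matrices of (x, y) coordinates.
#' @param spacing A [spacing()] (default: unit pixel spacing).
#' @return Numeric vector of `n` radial errors (mm or px).
#' @examples
#' radial_errors(cbind(3, 4), cbind(0, 0)) # 5
#' @export
radial_errors <- function(predicted, truth, spacing = NULL) {
  predicted <- as.matrix(predicted)
  truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth landmark counts differ")
  if (is.null(spacing)) spacing <- spacing(1, 1, "px")
  dx <- (predicted[, 1L] - truth[, 1L]) * spacing$sx
  dy <- (predicted[, 2L] - truth[, 2L]) * spacing$sy
  sqrt(dx^2 + dy^2)
}

#' Mean radial error
#'
#' Arithmetic mean and population standard deviation (divide by N) of a set
#' of radial errors.
#'
#' @param errors Non-empty numeric vector of radial errors.
#' @return Named vector `c(mre, std)`.
#' @export
mre <- function(errors) {
  if (length(errors) == 0L) stop("empty error vector")
  m <- mean(errors)
  c(mre = m, std = sqrt(mean((errors - m)^2)))
}

#' Successful detection rate
#'
#' Fraction of radial errors strictly below each threshold (an error exactly
#' equal to a threshold does not count), reported as a percentage.
#'
#' @param errors Numeric vector of radial errors.
#' @param thresholds Positive, sorted thresholds (mm or px).
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @examples
#' sdr(c(1, 2.5, 3), 2) # 33.33...
#' @export
sdr <- function(errors, thresholds) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  out <- vapply(thresholds, function(k) 100 * mean(errors < k), numeric(1L))
  names(out) <- paste0("<", thresholds)
  out
}

#' Default SDR reporting thresholds
#'
#' Standard grids for radiograph landmark reporting: `(2, 3, 4)` mm for
#' mm-calibrated domains and `(3, 6, 9)` px otherwise.
#'
#' @param units `"mm"` or `"px"`.
#' @return Numeric threshold vector.
#' @export
default_thresholds <- function(units = c("px", "mm")) {
  units <- match.arg(units)
  if (units == "mm") c(2, 3, 4) else c(3, 6, 9)
}

.eval_result <- function(errors, thresholds, units) {
  s <- mre(errors)
  structure(list(errors = errors, mre = unname(s["mre"]),
                 std = unname(s["std"]), sdr = sdr(errors, thresholds),
                 thresholds = thresholds, n = length(errors),
                 units = units),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n=%d  MRE %.3f +/- %.3f %s  SDR%%: %s\n",
              x$n, x$mre, x$std, x$units,
              paste(sprintf("%s:%.2f", names(x$sdr), x$sdr),
                    collapse = " ")))
  invisible(x)
}

#' Evaluate a model on one domain's test set
#'
#' Forward pass, argmax decoding of the final fused heatmap, and radial
#' errors under each sample's spacing, pooled over all (image, landmark)
#' pairs. Deterministic given a checkpoint.
#'
#' @param model A `gu2net` model.
#' @param test_set List of [landmark_sample()]s from one registered domain.
#' @param thresholds SDR thresholds; defaults to [default_thresholds()] of
#'   the set's units.
#' @param batch_size Forward batch size.
#' @return An `eval_result` with fields `errors`, `mre`, `std`, `sdr`
#'   (percentages), `n`, `units`.
#' @export
evaluate_model <- function(model, test_set, thresholds = NULL,
                           batch_size = 8L) {
  stopifnot(length(test_set) > 0L)
  dom <- test_set[[1L]]$domain_id
  .domain_row(model$config, dom)
  units <- test_set[[1L]]$spacing$unit
  if (is.null(thresholds)) thresholds <- default_thresholds(units)
  errs <- list()
  i <- 1L
  n <- length(test_set)
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    batch <- test_set[i:j]
    H <- nrow(batch[[1L]]$image); W <- ncol(batch[[1L]]$image)
    X <- .images_to_batch(lapply(batch, function(s)
      zscore_normalize(s$image)))
    out <- .forward_net(model, X, H, W, length(batch), dom,
                        training = FALSE)
    for (b in seq_along(batch)) {
      off <- (b - 1L) * H * W
      K <- nrow(out$final)
      pred <- matrix(0, K, 2L)
      for (k in seq_len(K)) {
        s <- which.max(out$final[k, off + seq_len(H * W)]) - 1L
        pred[k, ] <- c(s %% W, s %/% W)
      }
      errs[[length(errs) + 1L]] <-
        radial_errors(pred, batch[[b]]$landmarks, batch[[b]]$spacing)
    }
    i <- j + 1L
  }
  .eval_result(unlist(errs), thresholds, units)
}

#' Pool evaluation results across domains
#'
#' Concatenates the per-pair radial errors of several `eval_result`s, so the
#' pooled MRE equals the sample-weighted average of the per-domain MREs.
#'
#' @param results List of `eval_result`s sharing one threshold grid.
#' @return A pooled `eval_result` (units `"mixed"` if they differ).
#' @export
pool_eval_results <- function(results) {
  stopifnot(length(results) > 0L)
  thr <- results[[1L]]$thresholds
  for (r in results)
    if (!identical(r$thresholds, thr))
      stop("results use different threshold grids")
  units <- unique(vapply(results, `[[`, character(1L), "units"))
  units <- if (length(units) == 1L) units else "mixed"
  .eval_result(unlist(lapply(results, `[[`, "errors")), thr, units)
}

#' Cross-anatomy MRE matrix
#'
#' Entry `(i, j)` is the MRE on domain `j`'s test set after installing
#' domain `i`'s private parameters via [swap_domain_params()]; the diagonal
#' is the matched evaluation. Off-diagonal entries are expected to be far
#' above the diagonal: private parameters carry domain knowledge that does
#' not transfer across anatomies.
#'
#' @param model A trained multi-domain `gu2net` model.
#' @param test_sets List of test sets, one per domain id.
#' @return `t x t` numeric matrix of MREs (rows: parameter source domain;
#'   columns: evaluated domain).
#' @export
cross_anatomy_matrix <- function(model, test_sets) {
  ids <- vapply(test_sets, function(ts) ts[[1L]]$domain_id, integer(1L))
  t_ <- length(ids)
  M <- matrix(NA_real_, t_, t_,
              dimnames = list(paste0("params", ids), paste0("test", ids)))
  for (a in seq_len(t_)) {
    for (b in seq_len(t_)) {
      m <- if (ids[a] == ids[b]) model
           else swap_domain_params(model, ids[a], ids[b])
      M[a, b] <- evaluate_model(m, test_sets[[b]])$mre
    }
  }
  M
}

# restrict a benchmark to a subset of domains, remapping ids to 0..s-1
.subset_benchmark <- function(benchmark, dom_ids) {
  keep <- match(as.character(dom_ids), names(benchmark$train))
  remap <- function(sets, new_ids) {
    out <- lapply(seq_along(keep), function(i) {
      lapply(sets[[keep[i]]], function(s) {
        s$domain_id <- new_ids[i]
        s
      })
    })
    names(out) <- as.character(new_ids)
    out
  }
  new_ids <- seq_along(keep) - 1L
  doms <- benchmark$domains[match(dom_ids, benchmark$domains$domain_id), ,
                            drop = FALSE]
  doms$domain_id <- new_ids
  list(domains = doms,
       train = remap(benchmark$train, new_ids),
       val = remap(benchmark$val, new_ids),
       test = remap(benchmark$test, new_ids))
}

#' Domain-count sweep
#'
#' For each probe domain and each subset size `s`, trains one model per
#' `s`-subset of domains containing the probe, evaluates on the probe
#' domain's test set, and averages across subsets — quantifying how adding
#' anatomically distinct training domains affects a single domain's
#' accuracy.
#'
#' @param benchmark A benchmark as returned by [generate_benchmark()]
#'   (fields `domains`, `train`, `val`, `test`).
#' @param subset_sizes Integer vector of domain-set sizes to evaluate.
#' @param train_cfg A [train_config()].
#' @param net_args Extra arguments passed to [network_config()].
#' @param probe_ids Domains to probe (default: all).
#' @param max_subsets Cap on subsets per (probe, size) for bounded runtime.
#' @return A data.frame with one row per (probe, size, subset) holding the
#'   probe-domain MRE, plus aggregate rows via `attr(, "summary")`.
#' @export
domain_count_sweep <- function(benchmark, subset_sizes, train_cfg,
                               net_args = list(), probe_ids = NULL,
                               max_subsets = 3L) {
  ids <- benchmark$domains$domain_id
  if (is.null(probe_ids)) probe_ids <- ids
  if (any(subset_sizes > length(ids)))
    stop("subset size exceeds domain count")
  rows <- list()
  for (probe in probe_ids) {
    others <- setdiff(ids, probe)
    for (s in subset_sizes) {
      combos <- if (s == 1L) list(integer(0L))
                else utils::combn(others, s - 1L, simplify = FALSE)
      if (length(combos) > max_subsets)
        combos <- combos[seq_len(max_subsets)]
      for (ci in seq_along(combos)) {
        sub <- .subset_benchmark(benchmark, sort(c(probe, combos[[ci]])))
        cfg <- do.call(network_config,
                       c(list(domains = sub$domains,
                              seed = train_cfg$seed), net_args))
        fit <- train_model(build_model(cfg), sub$train, sub$val, train_cfg)
        new_probe <- sub$domains$domain_id[
          match(probe, sort(c(probe, combos[[ci]])))]
        ev <- evaluate_model(fit$model, sub$test[[as.character(new_probe)]])
        rows[[length(rows) + 1L]] <-
          data.frame(probe = probe, n_domains = s, subset = ci,
                     mre = ev$mre, std = ev$std)
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(mre ~ probe + n_domains, out, mean)
  attr(out, "summary") <- agg
  out
}
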