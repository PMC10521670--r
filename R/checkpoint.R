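# Model checkpoints: one directory holding the weights (shared + one group
# per domain) and a JSON manifest so checkpoints are introspectable without
# the code version that wrote them.

#' Save a model checkpoint
#'
#' Writes `weights.rds` (parameters and batch-norm running statistics,
#' grouped into shared and per-domain sets) and a human-readable
#' `manifest.json` carrying the configuration, the domain table, the epoch
#' and validation loss (when a [train_model()] result is given), and an md5
#' hash of the configuration.
#'
#' @param x A `gu2net` model or a `train_result`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(x, dir) {
  fit <- NULL
  if (inherits(x, "train_result")) {
    fit <- x
    x <- x$model
  }
  stopifnot(inherits(x, "gu2net"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- partition_params(x)
  saveRDS(list(params = x$params, bn = x$state$bn), file.path(dir,
                                                              "weights.rds"))
  cfg <- x$config
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "domains")],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    format = "uniland-checkpoint-1",
    variant = cfg$variant,
    domains = cfg$domains,
    config = cfg[setdiff(names(cfg), "domains")],
    config_md5 = unname(tools::md5sum(tmp)),
    n_params = unname(pp$counts$total),
    n_shared = unname(pp$counts$shared),
    n_per_domain = as.list(pp$counts$per_domain),
    epoch = if (!is.null(fit)) fit$best_epoch else NULL,
    val_loss = if (!is.null(fit) && nrow(fit$history))
      min(fit$history$val_pooled) else NULL
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return A `gu2net` model.
#' @export
load_checkpoint <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  w <- readRDS(file.path(dir, "weights.rds"))
  cfg <- man$config
  config <- network_config(
    domains = as.data.frame(man$domains),
    encoder_widths = cfg$encoder_widths,
    global_width = cfg$global_width,
    global_dilations = cfg$global_dilations,
    fusion_input_mode = cfg$fusion_input_mode,
    variant = cfg$variant, sigma = cfg$sigma,
    leaky_slope = cfg$leaky_slope, seed = cfg$seed
  )
  model <- structure(list(config = config, params = w$params,
                          state = .new_state()),
                     class = "gu2net")
  model$state$bn <- w$bn
  model
}
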