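# Gaussian heatmap codec: landmarks -> per-landmark probability maps and
# argmax decoding back to coordinates.

#' Construct a heatmap stack
#'
#' @param values Numeric array `height x width x num_landmarks` with entries
#'   in `[0, 1]`, indexed `[y + 1, x + 1, k]`.
#' @param sigma Gaussian width in pixels used to generate the stack.
#' @param gamma Scaling factor of the Gaussian prefactor `gamma / (2*pi*sigma)`.
#' @param role One of `"target"`, `"local"`, `"global"`, `"final"`.
#' @return An object of class `heatmap_stack`.
#' @export
heatmap_stack <- function(values, sigma = 3, gamma = 2 * pi * sigma,
                          role = c("target", "local", "global", "final")) {
  role <- match.arg(role)
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop("values must be an H x W x K array")
  if (min(values) < 0 || max(values) > 1)
    stop("heatmap values must lie in [0, 1]")
  structure(list(values = values, sigma = sigma, gamma = gamma, role = role),
            class = "heatmap_stack")
}

#' @export
print.heatmap_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<heatmap_stack> %s, %d channels, %dx%d, sigma=%g, gamma=%g\n",
              x$role, d[3L], d[2L], d[1L], x$sigma, x$gamma))
  invisible(x)
}

#' Encode landmarks as Gaussian heatmaps
#'
#' Channel `k` holds `gamma / (2*pi*sigma) * exp(-||p - x_k||^2 / (2*sigma^2))`
#' evaluated at every pixel centre `p`. With the default
#' `gamma = 2*pi*sigma` the prefactor is exactly 1, so the map peaks at 1 at
#' the landmark and the value range is `[0, 1]`; for landmarks at fractional
#' coordinates the grid maximum sits at the nearest integer pixel.
#'
#' @param landmarks Numeric `n x 2` matrix of 0-based (x, y) coordinates.
#' @param shape Image size `c(width, height)` the maps are evaluated on.
#' @param sigma Gaussian width in pixels (default 3).
#' @param gamma Prefactor scale; default `2*pi*sigma` for a unit peak.
#' @param role Role tag of the produced stack, default `"target"`.
#' @return A [heatmap_stack()] with one channel per landmark.
#' @examples
#' hs <- encode_heatmaps(cbind(8, 8), shape = c(16, 16))
#' hs$values[9, 9, 1] # exactly 1 at the landmark pixel
#' @export
encode_heatmaps <- function(landmarks, shape, sigma = 3,
                            gamma = 2 * pi * sigma, role = "target") {
  landmarks <- as.matrix(landmarks)
  W <- as.integer(shape[1L]); H <- as.integer(shape[2L])
  if (sigma <= 0) stop("sigma must be positive")
  if (any(landmarks[, 1L] < 0 | landmarks[, 1L] >= W |
          landmarks[, 2L] < 0 | landmarks[, 2L] >= H))
    stop("landmark outside the frame: validate the sample before encoding")
  peak <- gamma / (2 * pi * sigma)
  n <- nrow(landmarks)
  vals <- array(0, c(H, W, n))
  xs <- 0:(W - 1L); ys <- 0:(H - 1L)
  for (k in seq_len(n)) {
    dx2 <- (xs - landmarks[k, 1L])^2
    dy2 <- (ys - landmarks[k, 2L])^2
    vals[, , k] <- peak * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  }
  heatmap_stack(vals, sigma = sigma, gamma = gamma, role = role)
}

#' Decode landmarks from a heatmap stack
#'
#' Per channel, returns the (x, y) of the maximum value. Ties are broken by
#' row-major scan order (first occurrence scanning rows top to bottom, x
#' fastest), so a uniform channel decodes to (0, 0).
#'
#' @param stack A [heatmap_stack()] (or a bare H x W x K array).
#' @return Numeric `K x 2` matrix of 0-based (x, y) coordinates.
#' @export
decode_landmarks <- function(stack) {
  vals <- if (inherits(stack, "heatmap_stack")) stack$values else stack
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))
  K <- dim(vals)[3L]; W <- dim(vals)[2L]
  out <- matrix(0, K, 2L, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(K)) {
    v <- t(vals[, , k])           # linear index s = y*W + x, x fastest
    s <- which.max(v) - 1L
    out[k, ] <- c(s %% W, s %/% W)
  }
  out
}

#' Fuse local and global heatmaps
#'
#' Element-wise product of the two branches' stacks; the peak of the product
#' is attained where both factors are jointly large. Values stay in `[0, 1]`.
#'
#' @param local_stack,global_stack [heatmap_stack()]s of identical shape.
#' @return A [heatmap_stack()] with `role = "final"`.
#' @export
fuse_heatmaps <- function(local_stack, global_stack) {
  lv <- if (inherits(local_stack, "heatmap_stack")) local_stack$values else local_stack
  gv <- if (inherits(global_stack, "heatmap_stack")) global_stack$values else global_stack
  if (!identical(dim(lv), dim(gv)))
    stop("local and global stacks must have identical shapes")
  sg <- if (inherits(local_stack, "heatmap_stack")) local_stack$sigma else 3
  gm <- if (inherits(local_stack, "heatmap_stack")) local_stack$gamma else 2 * pi * sg
  heatmap_stack(lv * gv, sigma = sg, gamma = gm, role = "final")
}

#' Export a heatmap stack for inspection
#'
#' Writes the stack either as a multi-page 32-bit float TIFF (requires the
#' `tiff` package) or as an RDS array container.
#'
#' @param stack A [heatmap_stack()].
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.rds`).
#' @return `path`, invisibly.
#' @export
export_heatmaps <- function(stack, path) {
  stopifnot(inherits(stack, "heatmap_stack"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF export")
    pages <- lapply(seq_len(dim(stack$values)[3L]),
                    function(k) stack$values[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "rds") {
    saveRDS(stack, path)
  } else {
    stop("unsupported export format: .", ext)
  }
  invisible(path)
}
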