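# Domain registry and sample handling.
#
# Coordinate convention used everywhere in the package: 0-based pixel
# coordinates, x = column, y = row, pixel centre at integer coordinates.

#' Describe one anatomy/dataset domain
#'
#' A domain spec bundles everything the model and loaders need to know about
#' one dataset: how many landmarks it has, the working image size, and how
#' physical pixel spacing is obtained.
#'
#' @param name Domain name (unique within a registry).
#' @param num_landmarks Number of landmarks per image.
#' @param target_size Working image size `c(width, height)`; both must be
#'   divisible by 16 (the local branch halves resolution four times).
#' @param spacing_mode One of `"fixed_mm"` (constant mm/px), `"pixel"`
#'   (unit spacing, errors reported in px), or `"wrist_width_mm"` (isotropic
#'   spacing inferred from a reference width between two landmarks, as for
#'   hand radiographs with an assumed 50 mm wrist).
#' @param input_channels Image channels (1 for X-ray).
#' @param spacing_mm For `fixed_mm`: `c(sx, sy)` in mm/px at `target_size`.
#' @param reference_mm For `wrist_width_mm`: the physical reference width.
#' @param endpoints For `wrist_width_mm`: 1-based indices of the two
#'   landmarks spanning the reference width (hand set: points 1 and 5).
#' @param n_train,n_test Declared split sizes (bookkeeping only).
#' @param domain_id 0-based integer id; usually assigned by
#'   [register_domains()].
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name, num_landmarks, target_size,
                        spacing_mode = c("pixel", "fixed_mm", "wrist_width_mm"),
                        input_channels = 1L, spacing_mm = NULL,
                        reference_mm = NULL, endpoints = NULL,
                        n_train = 0L, n_test = 0L, domain_id = NA_integer_) {
  spacing_mode <- match.arg(spacing_mode)
  num_landmarks <- as.integer(num_landmarks)
  target_size <- as.integer(target_size)
  if (num_landmarks < 1L) stop("num_landmarks must be >= 1")
  if (length(target_size) != 2L || any(target_size < 8L))
    stop("target_size must be c(width, height) with components >= 8")
  if (any(target_size %% 16L != 0L))
    stop("target_size components must be divisible by 16 (domain '", name,
         "'): got ", paste(target_size, collapse = "x"))
  if (input_channels < 1L) stop("input_channels must be >= 1")
  if (spacing_mode == "fixed_mm") {
    if (is.null(spacing_mm) || length(spacing_mm) != 2L || any(spacing_mm <= 0))
      stop("fixed_mm mode needs spacing_mm = c(sx, sy) with positive entries")
  }
  if (spacing_mode == "wrist_width_mm") {
    if (is.null(reference_mm) || reference_mm <= 0)
      stop("wrist_width_mm mode needs a positive reference_mm")
    if (is.null(endpoints)) endpoints <- c(1L, 5L)
    if (length(endpoints) != 2L || endpoints[1L] == endpoints[2L])
      stop("endpoints must be two distinct 1-based landmark indices")
  }
  structure(list(
    domain_id = as.integer(domain_id), name = as.character(name),
    num_landmarks = num_landmarks, input_channels = as.integer(input_channels),
    target_size = target_size, spacing_mode = spacing_mode,
    spacing_mm = spacing_mm, reference_mm = reference_mm,
    endpoints = if (!is.null(endpoints)) as.integer(endpoints) else NULL,
    split = c(n_train = as.integer(n_train), n_test = as.integer(n_test))
  ), class = "domain_spec")
}

#' Register a set of domains
#'
#' Builds the immutable registry the rest of the package works against.
#' Accepts a list of [domain_spec()] objects or a path to a YAML file with a
#' top-level `domains:` list naming the same fields. Domain ids must be
#' unique and contiguous from 0; specs without an id are numbered in order.
#'
#' @param config A list of `domain_spec` objects, or a YAML file path.
#' @return An object of class `domain_registry`: a list of specs indexed by
#'   `domain_id + 1`, with attribute `t` = number of domains.
#' @examples
#' reg <- register_domains(list(
#'   domain_spec("head", 19, c(416, 512), "fixed_mm", spacing_mm = c(0.1, 0.1)),
#'   domain_spec("chest", 6, c(512, 512), "pixel")
#' ))
#' registry_size(reg)
#' @export
register_domains <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- .specs_from_yaml(config)
  if (!is.list(config) || length(config) == 0L)
    stop("config must declare at least one domain")
  if (inherits(config, "domain_spec")) config <- list(config)
  if (!all(vapply(config, inherits, logical(1L), "domain_spec")))
    stop("config must be a list of domain_spec objects or a YAML path")
  ids <- vapply(config, function(s) s$domain_id, integer(1L))
  if (all(is.na(ids))) ids <- seq_along(config) - 1L
  if (any(is.na(ids))) stop("either all or no domain_ids may be pre-assigned")
  if (anyDuplicated(ids)) stop("duplicate domain_id in registry")
  if (!setequal(ids, seq_along(config) - 1L))
    stop("domain_ids must be contiguous from 0")
  nms <- vapply(config, function(s) s$name, character(1L))
  if (anyDuplicated(nms)) stop("duplicate domain names in registry")
  specs <- config[order(ids)]
  for (i in seq_along(specs)) specs[[i]]$domain_id <- i - 1L
  names(specs) <- vapply(specs, function(s) s$name, character(1L))
  structure(specs, class = "domain_registry", t = length(specs))
}

#' Number of registered domains
#' @param registry A `domain_registry`.
#' @return Integer `t`.
#' @export
registry_size <- function(registry) {
  stopifnot(inherits(registry, "domain_registry"))
  attr(registry, "t")
}

#' @export
print.domain_registry <- function(x, ...) {
  cat("<domain_registry> t =", registry_size(x), "domains\n")
  for (s in x)
    cat(sprintf("  [%d] %-12s %3d landmarks  %dx%d  %s\n", s$domain_id,
                s$name, s$num_landmarks, s$target_size[1L], s$target_size[2L],
                s$spacing_mode))
  invisible(x)
}

.specs_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$domains)) stop("registry YAML needs a top-level 'domains' list")
  lapply(cfg$domains, function(d) {
    domain_spec(
      name = d$name, num_landmarks = d$num_landmarks,
      target_size = unlist(d$target_size),
      spacing_mode = d$spacing_mode %||% "pixel",
      input_channels = d$input_channels %||% 1L,
      spacing_mm = if (!is.null(d$spacing_mm)) unlist(d$spacing_mm),
      reference_mm = d$reference_mm,
      endpoints = if (!is.null(d$endpoints)) unlist(d$endpoints),
      n_train = d$split$train %||% 0L, n_test = d$split$test %||% 0L,
      domain_id = d$id %||% NA_integer_
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel spacing
#'
#' Physical size of one pixel in mm along x and y, or unit pixel spacing for
#' datasets without physical calibration.
#'
#' @param sx,sy mm per pixel along x and y (must be positive).
#' @param unit `"mm"` or `"px"`.
#' @return An object of class `spacing`.
#' @export
spacing <- function(sx = 1, sy = sx, unit = c("mm", "px")) {
  unit <- match.arg(unit)
  if (sx <= 0 || sy <= 0) stop("spacing components must be positive")
  structure(list(sx = sx, sy = sy, unit = unit), class = "spacing")
}

#' Spacing from an assumed wrist width
#'
#' For hand radiographs with no physical calibration the pixel spacing is
#' inferred from an assumed physical wrist width: the isotropic spacing is
#' `wrist_width_mm / ||a - b||` mm per pixel, where `a` and `b` are the two
#' wrist endpoints among the landmarks (points 1 and 5 of the 37-landmark
#' hand set).
#'
#' @param landmarks Numeric `n x 2` matrix of (x, y) pixel coordinates.
#' @param wrist_width_mm Assumed physical width, default 50 mm.
#' @param endpoint_indices 1-based indices of the two endpoint landmarks.
#' @return A [spacing()] in mm.
#' @examples
#' hand_spacing(rbind(c(0, 0), c(50, 0)), 50, c(1, 2)) # 1 mm/px
#' @export
hand_spacing <- function(landmarks, wrist_width_mm = 50,
                         endpoint_indices = c(1L, 5L)) {
  landmarks <- as.matrix(landmarks)
  if (any(endpoint_indices < 1L) || any(endpoint_indices > nrow(landmarks)))
    stop("endpoint_indices out of range")
  a <- landmarks[endpoint_indices[1L], ]
  b <- landmarks[endpoint_indices[2L], ]
  d <- sqrt(sum((a - b)^2))
  if (d == 0) stop("coincident wrist endpoints: spacing undefined")
  s <- wrist_width_mm / d
  spacing(s, s, "mm")
}

#' One image with its landmarks
#'
#' @param domain_id 0-based domain id.
#' @param image Numeric `height x width` intensity matrix.
#' @param landmarks Numeric `n x 2` matrix of 0-based (x, y) coordinates.
#' @param spacing A [spacing()].
#' @param source_id Free-form provenance string.
#' @return An object of class `landmark_sample`.
#' @export
landmark_sample <- function(domain_id, image, landmarks, spacing,
                            source_id = "") {
  landmarks <- as.matrix(landmarks)
  colnames(landmarks) <- c("x", "y")
  if (any(!is.finite(landmarks))) stop("non-finite landmark coordinates")
  if (any(!is.finite(image))) stop("non-finite image intensities")
  structure(list(domain_id = as.integer(domain_id), image = image,
                 landmarks = landmarks, spacing = spacing,
                 source_id = source_id),
            class = "landmark_sample")
}

#' Load one sample from disk
#'
#' Reads an image and its landmark file, validates the landmark count
#' against the domain spec, and attaches spacing according to the spec's
#' spacing mode (`fixed_mm`: the declared constant, rescaled from the
#' spec's target geometry only on [resize_sample()]; `pixel`: unit;
#' `wrist_width_mm`: computed from the landmarks via [hand_spacing()]).
#' The sample is returned in its original resolution.
#'
#' @param image_path Path to a PNG/JPEG image.
#' @param landmark_path Path to a CSV/JSON landmark file.
#' @param spec The [domain_spec()] the sample belongs to.
#' @return A [landmark_sample()].
#' @export
load_sample <- function(image_path, landmark_path, spec) {
  stopifnot(inherits(spec, "domain_spec"))
  img <- read_image(image_path)
  lm <- read_landmarks(landmark_path, n_expected = spec$num_landmarks)
  H <- nrow(img); W <- ncol(img)
  if (any(lm[, 1L] < 0 | lm[, 1L] >= W | lm[, 2L] < 0 | lm[, 2L] >= H))
    stop("landmark outside the image frame in ", landmark_path)
  sp <- switch(spec$spacing_mode,
    pixel = spacing(1, 1, "px"),
    fixed_mm = spacing(spec$spacing_mm[1L], spec$spacing_mm[2L], "mm"),
    wrist_width_mm = hand_spacing(lm, spec$reference_mm, spec$endpoints)
  )
  landmark_sample(spec$domain_id, img, lm, sp, source_id = image_path)
}

#' Resize a sample with coordinate and spacing rescaling
#'
#' Resamples the image bilinearly to `target_size` and maps every landmark
#' `(x, y)` to `(x * W_new / W_old, y * H_new / H_old)`. Spacing is rescaled
#' by the inverse factors, so physical distances between landmarks are
#' preserved (spacing may become anisotropic).
#'
#' @param sample A [landmark_sample()].
#' @param target_size `c(width, height)` in pixels.
#' @return The resized [landmark_sample()].
#' @export
resize_sample <- function(sample, target_size) {
  stopifnot(inherits(sample, "landmark_sample"))
  target_size <- as.integer(target_size)
  if (length(target_size) != 2L || any(target_size <= 0))
    stop("target_size must be positive c(width, height)")
  Wo <- ncol(sample$image); Ho <- nrow(sample$image)
  Wn <- target_size[1L]; Hn <- target_size[2L]
  fx <- Wn / Wo; fy <- Hn / Ho
  lm <- sample$landmarks
  lm[, 1L] <- lm[, 1L] * fx
  lm[, 2L] <- lm[, 2L] * fy
  if (any(lm[, 1L] < 0 | lm[, 1L] >= Wn | lm[, 2L] < 0 | lm[, 2L] >= Hn))
    stop("landmark outside the frame after resize (was it in-bounds before?)")
  img <- .mat_to_image(cpp_resize_bilinear(.image_to_mat(sample$image),
                                           Ho, Wo, 1L, Hn, Wn), Hn, Wn)
  sp <- sample$spacing
  sp$sx <- sp$sx / fx
  sp$sy <- sp$sy / fy
  landmark_sample(sample$domain_id, img, lm, sp, sample$source_id)
}

#' Z-score intensity normalization
#'
#' Centres and scales an image to zero mean and unit (population) standard
#' deviation. Constant images map to all zeros rather than raising, so blank
#' synthetic borders cannot crash loading.
#'
#' @param image Numeric intensity matrix.
#' @return The normalized matrix.
#' @export
zscore_normalize <- function(image) {
  if (length(image) < 2L) stop("image must have more than one pixel")
  mu <- mean(image)
  sd_pop <- sqrt(mean((image - mu)^2))
  if (sd_pop == 0) return(image * 0)
  (image - mu) / sd_pop
}

# image (H x W matrix) <-> internal 1 x (H*W) channel-row layout
.image_to_mat <- function(img) matrix(as.numeric(t(img)), nrow = 1L)
.mat_to_image <- function(m, H, W) t(matrix(as.numeric(m), nrow = W, ncol = H))
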