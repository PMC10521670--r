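#' Read a grayscale radiograph image
#'
#' Reads an 8- or 16-bit PNG or JPEG image and returns a numeric matrix of
#' intensities in `[0, 1]`, one row per image row (row = y, column = x).
#' Colour images are converted to grayscale by channel averaging.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A numeric `height x width` matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (PNG/JPEG only)")
  )
  if (length(dim(img)) == 3L) {
    # drop alpha if present, then average colour channels
    nc <- min(dim(img)[3L], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  storage.mode(img) <- "double"
  img
}

#' Read landmark coordinates
#'
#' Landmark files are either CSV with a header `x,y` and one row per landmark
#' in canonical landmark order, or JSON of the form
#' `{"landmarks": [[x, y], ...]}`. Coordinates are 0-based pixel coordinates
#' (x = column, y = row, pixel centres at integers).
#'
#' @param path Path to a `.csv` or `.json` landmark file.
#' @param n_expected Optional landmark count to validate against.
#' @return A numeric `n x 2` matrix with columns `x` and `y`.
#' @export
read_landmarks <- function(path, n_expected = NULL) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
      stop("landmark CSV must have columns 'x' and 'y': ", path)
    lm <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$landmarks))
      stop("landmark JSON must hold a 'landmarks' array: ", path)
    lm <- matrix(as.numeric(t(obj$landmarks)), ncol = 2L, byrow = TRUE)
    colnames(lm) <- c("x", "y")
  } else {
    stop("unsupported landmark format: .", ext, " (CSV/JSON only)")
  }
  if (any(!is.finite(lm))) stop("non-finite landmark coordinates in ", path)
  if (!is.null(n_expected) && nrow(lm) != n_expected)
    stop("expected ", n_expected, " landmarks, found ", nrow(lm), " in ", path)
  lm
}

#' Write landmark coordinates as CSV
#'
#' Writes the same CSV dialect that [read_landmarks()] consumes
#' (header `x,y`, one row per landmark).
#'
#' @param landmarks Numeric `n x 2` matrix of (x, y) coordinates.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- as.matrix(landmarks)
  df <- data.frame(x = landmarks[, 1L], y = landmarks[, 2L])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
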