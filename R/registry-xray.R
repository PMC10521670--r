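#' Registry of the four standard radiograph landmark datasets
#'
#' The bundled registry of the four X-ray domains the full-size model is
#' designed for: lateral cephalograms (19 landmarks, 0.1 mm pixels, working
#' size 416x512), hand radiographs (37 landmarks, spacing inferred from an
#' assumed 50 mm wrist width between landmarks 1 and 5, 352x512), chest
#' radiographs (6 lung-field landmarks, 512x512, pixel units), and pelvis
#' radiographs (10 landmarks, 512x512, pixel units). The image data are
#' external drop-ins via the same layout; this registry carries geometry
#' and split bookkeeping only, which is all the architecture and parameter
#' accounting need.
#'
#' @return A [register_domains()] registry with `t = 4`.
#' @examples
#' reg <- xray_registry()
#' sum(vapply(reg, function(s) s$num_landmarks, integer(1))) # 72 landmarks
#' @export
xray_registry <- function() {
  register_domains(system.file("extdata", "registry_xray.yaml",
                               package = "uniland", mustWork = TRUE))
}
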