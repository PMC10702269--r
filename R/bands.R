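#' Physiologic frequency bands
#'
#' The five bands used for feature extraction. Edges (Hz): delta 0.5-4,
#' theta 4-8, alpha 8-12, beta 12-25, gamma 25-45.
#'
#' @param names optional subset of band names to return, in canonical order.
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
band_specs <- function(names = NULL) {
  bands <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(0.5, 4, 8, 12, 25),
    hi   = c(4, 8, 12, 25, 45),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    if (!all(names %in% bands$name))
      stop("unknown band name(s): ", paste(setdiff(names, bands$name), collapse = ", "))
    bands <- bands[match(names, bands$name), , drop = FALSE]
    rownames(bands) <- NULL
  }
  bands
}

validate_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo <= 0) || any(bands$hi <= bands$lo))
    stop("band edges must satisfy 0 < lo < hi")
  if (any(bands$hi >= fs / 2))
    stop(sprintf("band upper edge must be below the Nyquist frequency (%g Hz)", fs / 2))
  invisible(bands)
}
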