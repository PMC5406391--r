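#' The 14-channel consumer headset montage
#'
#' Electrode labels and approximate scalp coordinates for the 14-channel
#' subset of the international 10-20 system used throughout the package
#' (AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4).
#' Coordinates live in a unit head circle; `x` is lateral (right positive),
#' `y` is anterior-posterior (front positive), and left/right homologues
#' mirror in `x`.
#'
#' @return A tibble with columns `channel`, `x`, `y`, one row per electrode,
#'   in the canonical channel order used for all feature columns.
#' @examples
#' montage_channels()
#' @export
montage_channels <- function() {
  tibble::tibble(
    channel = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
    x = c(-0.30, -0.71, -0.35, -0.59, -0.81, -0.71, -0.26,
           0.26,  0.71,  0.81,  0.59,  0.35,  0.71,  0.30),
    y = c( 0.79,  0.44,  0.45,  0.21,  0.00, -0.44, -0.77,
          -0.77, -0.44,  0.00,  0.21,  0.45,  0.44,  0.79)
  )
}

#' Frontal channels used by the blink-topography artifact rule
#' @keywords internal
frontal_channels <- function() c("AF3", "AF4", "F7", "F8")

#' Canonical EEG frequency bands
#'
#' The four rhythmic bands the analysis decomposes each channel into:
#' theta 4-7 Hz, alpha 8-15 Hz, beta 16-31 Hz and gamma 32-45 Hz.
#' Band-power sums treat both edges as inclusive.
#'
#' @return A tibble with columns `band` (ordered factor levels
#'   theta < alpha < beta < gamma), `lo_hz`, `hi_hz`.
#' @examples
#' band_definitions()
#' @export
band_definitions <- function() {
  tibble::tibble(
    band  = c("theta", "alpha", "beta", "gamma"),
    lo_hz = c(4, 8, 16, 32),
    hi_hz = c(7, 15, 31, 45)
  )
}

band_names <- function() band_definitions()$band

#' Look up one band definition by name
#' @param name One of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return A one-row tibble with `band`, `lo_hz`, `hi_hz`.
#' @export
band_definition <- function(name) {
  bands <- band_definitions()
  if (!name %in% bands$band) {
    stop("unknown band '", name, "'; expected one of ",
         paste(bands$band, collapse = ", "), call. = FALSE)
  }
  bands[bands$band == name, ]
}
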