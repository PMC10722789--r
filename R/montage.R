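#' EEG montages
#'
#' A montage names the channel set of a recording, 2-D head-plane coordinates
#' used for bad-channel interpolation, the "skirt" channels (the outermost ring
#' of a high-density net, routinely excluded for muscle and movement
#' contamination), the mastoid labels used for re-referencing, and the frontal
#' channels used as the blink-regression template.
#'
#' Two montages ship with the package:
#' \describe{
#'   \item{`desk32`}{a 32-channel 10-20-style cap (8 skirt channels, mastoids
#'     `M1`/`M2`, frontal pair `Fp1`/`Fp2`); the default simulation profile.}
#'   \item{`egi128`}{a 128-channel geodesic-style net laid out in concentric
#'     rings (`E1`..`E128`); its outermost ring of 46 channels is the default
#'     skirt list, so 82 channels are retained for analysis. The skirt list is
#'     a documented default and can be overridden via the `skirt` argument.}
#' }
#'
#' @param name Montage name, `"desk32"` or `"egi128"`.
#' @param skirt Optional character vector overriding the default skirt list.
#' @return An object of class `eeg_montage`: a list with elements `name`,
#'   `channels` (a tibble with `label`, `x`, `y`), `skirt`, `mastoids`,
#'   `frontal`.
#' @examples
#' m <- build_montage("egi128")
#' length(setdiff(m$channels$label, m$skirt)) # 82 retained channels
#' @export
build_montage <- function(name = c("desk32", "egi128"), skirt = NULL) {
  name <- match.arg(name)
  if (name == "desk32") {
    channels <- tibble::tribble(
      ~label, ~x, ~y,
      "Fp1", -0.31, 0.95, "Fp2", 0.31, 0.95,
      "F7", -0.81, 0.59, "F3", -0.40, 0.54, "Fz", 0, 0.55, "F4", 0.40, 0.54, "F8", 0.81, 0.59,
      "FT7", -0.84, 0.31, "FC3", -0.42, 0.28, "FCz", 0, 0.28, "FC4", 0.42, 0.28, "FT8", 0.84, 0.31,
      "T7", -1.00, 0.00, "C3", -0.45, 0, "Cz", 0, 0, "C4", 0.45, 0, "T8", 1.00, 0.00,
      "TP7", -0.84, -0.31, "CP3", -0.42, -0.28, "CPz", 0, -0.28, "CP4", 0.42, -0.28, "TP8", 0.84, -0.31,
      "P7", -0.81, -0.59, "P3", -0.40, -0.54, "Pz", 0, -0.55, "P4", 0.40, -0.54, "P8", 0.81, -0.59,
      "O1", -0.31, -0.95, "Oz", 0, -1.00, "O2", 0.31, -0.95,
      "M1", -1.05, -0.50, "M2", 1.05, -0.50
    )
    default_skirt <- c("F7", "F8", "T7", "T8", "P7", "P8", "O1", "O2")
    mastoids <- c("M1", "M2")
    frontal <- c("Fp1", "Fp2")
  } else {
    # concentric rings, centre outward; the outermost ring (46 labels) is the skirt
    ring_sizes <- c(1, 8, 14, 19, 40, 46)
    radii <- c(0, 0.18, 0.36, 0.54, 0.75, 1.0)
    pos <- purrr::map2_dfr(ring_sizes, radii, function(k, r) {
      ang <- if (k == 1) 0 else seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] + pi / 2
      tibble::tibble(x = round(r * cos(ang), 4), y = round(r * sin(ang), 4))
    })
    channels <- dplyr::mutate(pos, label = paste0("E", dplyr::row_number()), .before = 1)
    default_skirt <- paste0("E", 83:128)
    # the two ring-5 electrodes closest to the mastoid positions (lower lateral)
    ring5 <- channels$label[43:82]
    mast_xy <- list(c(-0.9, -0.55), c(0.9, -0.55))
    mastoids <- vapply(mast_xy, function(p) {
      d <- (channels$x[43:82] - p[1])^2 + (channels$y[43:82] - p[2])^2
      ring5[which.min(d)]
    }, character(1))
    frontal <- setdiff(channels$label[order(-channels$y)], default_skirt)[1:2]
  }
  if (!is.null(skirt)) {
    bad <- setdiff(skirt, channels$label)
    if (length(bad)) stop("unknown skirt channels: ", paste(bad, collapse = ", "))
    default_skirt <- skirt
  }
  if (any(mastoids %in% default_skirt)) {
    stop("mastoid channels cannot be in the skirt list")
  }
  structure(
    list(name = name, channels = channels, skirt = default_skirt,
         mastoids = mastoids, frontal = frontal),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf(
    "<eeg_montage %s: %d channels, %d skirt, mastoids %s, retained %d>\n",
    x$name, nrow(x$channels), length(x$skirt),
    paste(x$mastoids, collapse = "/"),
    nrow(x$channels) - length(x$skirt)
  ))
  invisible(x)
}

#' Channels retained after skirt exclusion
#'
#' @param montage An [build_montage()] object.
#' @return Character vector of retained channel labels.
#' @export
retained_channels <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  setdiff(montage$channels$label, montage$skirt)
}
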