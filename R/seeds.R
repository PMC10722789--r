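#' Derive a named sub-seed from a master seed
#'
#' Every random draw site in the package takes its own sub-seed derived from a
#' master seed and a site name, so adding a new draw site never perturbs the
#' streams of existing ones. The derivation is a 32-bit FNV-1a hash of the site
#' name mixed with the master seed, reduced modulo `2^31 - 1` (R integers are
#' 32-bit signed).
#'
#' @param seed Integer master seed.
#' @param name Character scalar naming the draw site (e.g. `"session-TD01"`).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "roster")
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name), length(name) == 1)
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit multiply by the FNV prime 16777619, done in double with explicit wrap
    h <- (h * 16777619) %% 4294967296
  }
  h <- (h + abs(as.numeric(seed)) * 2654435761) %% 4294967296
  as.integer(h %% (2^31 - 1))
}
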