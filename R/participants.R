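#' Sample a participant roster
#'
#' Draws a synthetic cohort with the configured per-group sizes. Sex is
#' Bernoulli with per-group female probabilities (defaults 4/23, 1/17, 22/45);
#' age and IQ are truncated normals with the configured group means and SDs
#' (IQ truncated to `[20, 160]`, age to `[3, 5]`; full-scale IQ additionally
#' respects the diagnostic bound: below 70 for the ASD-with-DD group, at or
#' above 70 otherwise). The latent social trait is Normal(group mean, group
#' SD). Clinical severity scores (CARS total, ADOS-CSS) are affine functions of
#' the trait plus noise and are generated only for the ASD groups.
#'
#' @param config A [default_config()] list.
#' @param seed Integer seed; the draw is fully deterministic given
#'   `(config, seed)`.
#' @return A tibble with one row per participant: `id`, `group`, `sex`, `age`,
#'   `viq`, `piq`, `fsiq`, `cars_total`, `ados_css` (NA for TD), `trait`.
#' @examples
#' roster <- sample_participants(default_config(), seed = 42)
#' nrow(roster) # 85
#' @export
sample_participants <- function(config, seed) {
  validate_config(config)
  set.seed(derive_seed(seed, "roster"))
  iq_rng <- config$analysis$iq_range
  age_rng <- config$analysis$age_range
  sev <- config$severity

  rows <- purrr::imap(config$groups, function(grp, gname) {
    n <- grp$n
    if (n == 0) return(NULL)
    fsiq_rng <- if (gname == "ASD_DD") c(iq_rng[1], 70 - 1e-9) else c(70, iq_rng[2])
    tibble::tibble(
      id = sprintf("%s-%02d", gname, seq_len(n)),
      group = gname,
      sex = ifelse(stats::runif(n) < grp$female_p, "female", "male"),
      age = rtruncnorm(n, grp$age["mean"], grp$age["sd"], age_rng[1], age_rng[2]),
      viq = rtruncnorm(n, grp$viq["mean"], grp$viq["sd"], iq_rng[1], iq_rng[2]),
      piq = rtruncnorm(n, grp$piq["mean"], grp$piq["sd"], iq_rng[1], iq_rng[2]),
      fsiq = rtruncnorm(n, grp$fsiq["mean"], grp$fsiq["sd"], fsiq_rng[1], fsiq_rng[2]),
      trait = stats::rnorm(n, grp$trait_mean, grp$trait_sd)
    )
  })
  roster <- dplyr::bind_rows(rows)
  is_asd <- roster$group %in% c("ASD_DD", "ASD_noDD")
  n_asd <- sum(is_asd)
  cars <- rep(NA_real_, nrow(roster))
  css <- rep(NA_real_, nrow(roster))
  if (n_asd > 0) {
    cars[is_asd] <- pmin(60, pmax(15, sev$cars_intercept - sev$cars_slope * roster$trait[is_asd] +
      stats::rnorm(n_asd, 0, sev$cars_sd)))
    mu_asd <- mean(vapply(config$groups[c("ASD_DD", "ASD_noDD")],
                          function(g) g$trait_mean, numeric(1)))
    css[is_asd] <- pmin(10, pmax(1, round(sev$css_intercept -
      sev$css_slope * (roster$trait[is_asd] - mu_asd) +
      stats::rnorm(n_asd, 0, sev$css_sd))))
  }
  roster$cars_total <- cars
  roster$ados_css <- css
  dplyr::relocate(roster, "trait", .after = "ados_css")
}

# truncated normal via inverse-CDF (deterministic, no rejection loop)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Write / read a roster CSV
#'
#' Columns: `id, group, sex, age, viq, piq, fsiq, cars_total, ados_css`
#' (the latent trait is a generator internal and is not serialized).
#'
#' @param roster A roster tibble from [sample_participants()].
#' @param path File path.
#' @return `write_roster` returns `path` invisibly; `read_roster` a tibble.
#' @export
write_roster <- function(roster, path) {
  out <- dplyr::select(roster, dplyr::all_of(c(
    "id", "group", "sex", "age", "viq", "piq", "fsiq", "cars_total", "ados_css"
  )))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = "c", group = "c", sex = "c",
                    .default = readr::col_double()
                  ))
}
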