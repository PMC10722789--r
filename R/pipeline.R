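#' Simulate a full cohort and compute per-participant measures
#'
#' Generates the roster, one coded play session per participant (scored into
#' the five indicators) and, optionally, the simultaneous EEG (preprocessed,
#' PSD, theta/alpha grand means). Raw and analysis-scale (square-root) values
#' are both returned.
#'
#' @param config A [default_config()] list.
#' @param seed Master seed; all per-participant draws use named sub-seeds.
#' @param eeg If `FALSE`, skip EEG simulation (behavioral columns only).
#' @return A tibble: roster columns plus `sic`, `it`, `rsc`, `gis`, `cis`,
#'   `rsc_defined`, and (with `eeg = TRUE`) `theta_raw`, `alpha_raw` (uV^2/Hz)
#'   and `theta`, `alpha` (analysis scale), `n_epochs_kept`.
#' @export
simulate_cohort <- function(config, seed, eeg = TRUE) {
  validate_config(config)
  roster <- sample_participants(config, seed)
  meas <- purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    s <- simulate_dyad_session(p, config, seed)
    ind <- score_sessions(s,
                          response_window = config$analysis$response_window,
                          gap_close = config$analysis$gap_close,
                          frame = config$session$frame)
    out <- dplyr::select(ind, -"session_id", -"participant_id", -"n_frames")
    if (eeg) {
      rec <- simulate_eeg(p, config, seed)
      epo <- preprocess(rec)
      psd <- compute_psd(epo)
      out$theta_raw <- band_power(psd, "theta")$grand
      out$alpha_raw <- band_power(psd, "alpha")$grand
      out$n_epochs_kept <- dim(epo$epochs)[1]
    }
    out
  })
  res <- dplyr::bind_cols(roster, meas)
  if (eeg) {
    res$theta <- sqrt_transform(res$theta_raw)
    res$alpha <- sqrt_transform(res$alpha_raw)
  }
  res
}

INDICATOR_COLS <- c("sic", "it", "rsc", "gis", "cis")

#' Run the full simulated study
#'
#' Orchestrates simulate, score, PSD and statistics into one reproducible run
#' that mirrors the study's report surface: a demographics table with group
#' ANOVAs; raw and sex-adjusted group comparisons for the five behavioral
#' indicators and the two band PSDs (models fitted on the square-root analysis
#' scale, means reported on both scales); ROC screening accuracy of every
#' indicator for three contrasts (all ASD vs TD, ASD without DD vs TD, ASD
#' with DD vs TD) with Youden-optimal cutoffs; partial correlations of each
#' indicator with each band PSD controlling for sex, and for sex plus verbal
#' IQ, Bonferroni-adjusted over the 10-test indicator-by-band family;
#' indicator-severity correlations per ASD group (sex-adjusted, raw and
#' analysis scale); and sex-stratified correlations.
#'
#' @param config A [default_config()] list (or path to a YAML config).
#' @param seed Master seed; reruns with identical `(config, seed)` are
#'   bit-identical.
#' @param out_dir If non-NULL, [export_report()] is called on the result.
#' @return An object of class `study_run`: list with `config`, `seed`,
#'   `roster`, `analysis` (per-participant tibble) and `tables` (named list of
#'   result tibbles), plus `provenance`.
#' @export
run_study <- function(config = default_config(), seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  analysis <- simulate_cohort(config, seed, eeg = TRUE)
  analysis$is_asd <- analysis$group %in% c("ASD_DD", "ASD_noDD")

  tables <- list()
  tables$demographics <- purrr::map_dfr(
    c("age", "viq", "piq", "fsiq", "cars_total", "ados_css"),
    function(v) {
      d <- analysis[!is.na(analysis[[v]]), ]
      if (length(unique(d$group)) < 2) return(NULL)
      glance_row <- glance(compare_groups(d, v, "group", "sex", ref = "TD"))
      means <- tidy(compare_groups(d, v, "group", "sex", ref = "TD"))[,
        c("variable", "group", "n", "mean", "se")]
      dplyr::left_join(means, glance_row[, c("variable", "statistic", "p.value")],
                       by = "variable")
    })

  band_cols <- c(theta = "theta", alpha = "alpha")
  tables$group_comparisons <- purrr::map_dfr(
    c(INDICATOR_COLS, "theta", "alpha"),
    function(v) {
      raw_col <- if (v %in% INDICATOR_COLS) v else paste0(v, "_raw")
      d <- analysis
      d$.value_sqrt <- sqrt_transform(d[[raw_col]])
      raw_means <- tidy(compare_groups(d, raw_col, "group", "sex", ref = "TD",
                                       variable = v))[,
        c("variable", "group", "n", "mean", "se")]
      adj <- compare_groups(d, ".value_sqrt", "group", "sex", ref = "TD",
                            variable = v)
      out <- dplyr::left_join(
        raw_means,
        tidy(adj)[, c("group", "adj_diff", "p_raw", "p_adj")],
        by = "group")
      out$f_statistic <- adj$f_statistic
      out$p_anova <- adj$p_anova
      out
    })

  contrasts <- list(
    full_sample = c("ASD_DD", "ASD_noDD"),
    asd_noDD_vs_td = "ASD_noDD",
    asd_DD_vs_td = "ASD_DD"
  )
  tables$roc <- purrr::map_dfr(names(contrasts), function(cn) {
    keep <- analysis$group %in% c(contrasts[[cn]], "TD")
    purrr::map_dfr(INDICATOR_COLS, function(v) {
      d <- analysis[keep & !is.na(analysis[[v]]), ]
      g <- glance(roc_analysis(d[[v]], d$is_asd))
      dplyr::bind_cols(tibble::tibble(contrast = cn, indicator = v), g)
    })
  })

  sexn <- as.integer(analysis$sex == "female")
  corr_one <- function(d, xcol, ycol, covs, label) {
    pc <- partial_pearson(d[[xcol]], d[[ycol]], covariates = covs,
                          names = c(xcol, ycol))
    dplyr::mutate(tidy(pc), adjustment = label, .before = 1)
  }
  tables$correlations <- purrr::map_dfr(c("sex", "sex+viq"), function(adj) {
    rows <- purrr::map_dfr(INDICATOR_COLS, function(v) {
      purrr::map_dfr(names(band_cols), function(b) {
        d <- analysis
        d$.x <- sqrt_transform(d[[v]])
        d$.y <- d[[b]]
        covs <- if (adj == "sex") cbind(sex = sexn) else
          cbind(sex = sexn, viq = analysis$viq)
        ok <- !is.na(d$.x)
        corr_one(d[ok, ], ".x", ".y", covs[ok, , drop = FALSE], adj) |>
          dplyr::mutate(x = v, y = b)
      })
    })
    rows$p_bonferroni <- bonferroni_adjust(p = rows$p.value, m = 10)
    rows
  })

  tables$severity <- purrr::map_dfr(c("ASD_DD", "ASD_noDD"), function(gname) {
    d <- analysis[analysis$group == gname, ]
    purrr::map_dfr(INDICATOR_COLS, function(v) {
      purrr::map_dfr(c("cars_total", "ados_css"), function(sv) {
        purrr::map_dfr(c("raw", "sqrt"), function(scale) {
          x <- if (scale == "raw") d[[v]] else sqrt_transform(d[[v]])
          ok <- !is.na(x) & !is.na(d[[sv]])
          if (sum(ok) < 5 || stats::sd(x[ok]) == 0) return(NULL)
          covs <- cbind(sex = as.integer(d$sex == "female"))[ok, , drop = FALSE]
          if (stats::sd(covs[, 1]) == 0) covs <- NULL
          pc <- partial_pearson(x[ok], d[[sv]][ok], covariates = covs,
                                names = c(v, sv))
          dplyr::mutate(tidy(pc), group = gname, scale = scale, .before = 1)
        })
      })
    })
  })

  tables$sex_stratified <- purrr::map_dfr(c("male", "female"), function(sx) {
    d <- analysis[analysis$sex == sx & analysis$is_asd, ]
    purrr::map_dfr(INDICATOR_COLS, function(v) {
      x <- sqrt_transform(d[[v]])
      ok <- !is.na(x) & !is.na(d$cars_total)
      if (sum(ok) < 6 || stats::sd(x[ok]) == 0) return(NULL)
      pc <- partial_pearson(x[ok], d$cars_total[ok],
                            covariates = cbind(viq = d$viq[ok]),
                            names = c(v, "cars_total"))
      dplyr::mutate(tidy(pc), sex = sx, .before = 1)
    })
  })

  run <- structure(list(
    config = config, seed = seed,
    roster = dplyr::select(analysis, "id":"trait"),
    analysis = analysis, tables = tables,
    provenance = list(seed = seed,
                      package_version = as.character(utils::packageVersion("dyadscreen")),
                      n_participants = nrow(analysis),
                      profile = config$profile)
  ), class = "study_run")
  if (!is.null(out_dir)) export_report(run, out_dir)
  run
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("<study_run: seed %s, %d participants, %d result tables>\n",
              format(x$seed), nrow(x$analysis), length(x$tables)))
  invisible(x)
}

#' Export a study run to report artifacts
#'
#' Writes each result table as CSV and JSON, renders the ROC curves (one
#' figure per contrast), an indicator group-comparison figure and a band-PSD
#' figure as PNG, and a markdown summary with the seed and package version.
#'
#' @param run A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
export_report <- function(run, out_dir) {
  stopifnot(inherits(run, "study_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  wr <- function(tbl, name) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    js <- file.path(out_dir, paste0(name, ".json"))
    readr::write_csv(tbl, csv)
    jsonlite::write_json(tbl, js, digits = NA, na = "null")
    files <<- c(files, csv, js)
  }
  for (nm in names(run$tables)) wr(run$tables[[nm]], nm)
  wr(dplyr::select(run$analysis, -dplyr::any_of("trait")), "per_participant")

  an <- run$analysis
  an$is_asd <- an$group %in% c("ASD_DD", "ASD_noDD")
  contrasts <- list(full_sample = c("ASD_DD", "ASD_noDD"),
                    asd_noDD_vs_td = "ASD_noDD", asd_DD_vs_td = "ASD_DD")
  for (cn in names(contrasts)) {
    keep <- an$group %in% c(contrasts[[cn]], "TD")
    curves <- purrr::map_dfr(INDICATOR_COLS, function(v) {
      d <- an[keep & !is.na(an[[v]]), ]
      r <- roc_analysis(d[[v]], d$is_asd)
      dplyr::mutate(tidy(r), indicator = toupper(v),
                    auc = r$auc)
    })
    gp <- ggplot2::ggplot(curves,
      ggplot2::aes(1 - .data$specificity, .data$sensitivity, color = .data$indicator)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey70") +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_equal() +
      ggplot2::labs(title = paste("ROC:", cn), x = "1 - specificity",
                    y = "Sensitivity", color = "Indicator") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, paste0("roc_", cn, ".png"))
    ggplot2::ggsave(f, gp, width = 5.5, height = 5, dpi = 120)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "indicators_by_group.png")
  ggplot2::ggsave(f, plot_indicator_groups(an), width = 7, height = 4.5, dpi = 120)
  files <- c(files, f)
  f <- file.path(out_dir, "band_psd_by_group.png")
  ggplot2::ggsave(f, plot_band_psd_groups(an), width = 5, height = 4.5, dpi = 120)
  files <- c(files, f)

  md <- file.path(out_dir, "summary.md")
  roc_full <- run$tables$roc[run$tables$roc$contrast == "full_sample", ]
  writeLines(c(
    "# Simulated caregiver-child interaction screening study",
    "",
    sprintf("- seed: %s", format(run$seed)),
    sprintf("- dyadscreen version: %s", run$provenance$package_version),
    sprintf("- participants: %d (%s)", nrow(an),
            paste(names(table(an$group)), table(an$group), sep = "=", collapse = ", ")),
    sprintf("- EEG profile: %s (%s @ %g Hz)", run$config$profile,
            run$config$eeg$montage, run$config$eeg$fs),
    "",
    "## Full-sample screening accuracy (Youden cutoff)",
    "",
    paste(utils::capture.output(print(as.data.frame(
      roc_full[, c("indicator", "auc", "sensitivity", "specificity", "accuracy")]
    ), digits = 3)), collapse = "\n")
  ), md)
  files <- c(files, md)
  invisible(files)
}
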