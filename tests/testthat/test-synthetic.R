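test_that("roster has the configured sizes, bounds and determinism", {
  cfg <- default_config()
  r <- sample_participants(cfg, 42)
  expect_equal(nrow(r), 85)
  expect_equal(as.vector(table(r$group)[c("ASD_DD", "ASD_noDD", "TD")]),
               c(23, 17, 45))
  expect_true(all(r$fsiq[r$group == "ASD_DD"] < 70))
  expect_true(all(r$fsiq[r$group != "ASD_DD"] >= 70))
  expect_true(all(r$fsiq > 0 & r$viq >= 20 & r$piq <= 160))
  expect_true(all(r$age >= 3 & r$age <= 5))
  expect_true(all(is.na(r$cars_total[r$group == "TD"])))
  asd <- r$group != "TD"
  expect_true(all(!is.na(r$cars_total[asd])))
  expect_true(all(r$ados_css[asd] >= 1 & r$ados_css[asd] <= 10))
  expect_identical(r, sample_participants(cfg, 42))
  expect_false(identical(r$trait, sample_participants(cfg, 43)$trait))
})

test_that("degenerate config with only TD participants works", {
  cfg <- default_config()
  cfg$groups$ASD_DD$n <- 0
  cfg$groups$ASD_noDD$n <- 0
  r <- sample_participants(cfg, 1)
  expect_equal(nrow(r), 45)
  expect_true(all(r$group == "TD"))
  expect_true(all(is.na(r$cars_total)))
  cfg$groups$TD$n <- -1
  expect_error(sample_participants(cfg, 1), "configuration error")
})

test_that("female counts match the configured per-group probabilities", {
  cfg <- default_config()
  counts <- vapply(1:400, function(s) {
    r <- sample_participants(cfg, s)
    sum(r$sex[r$group == "ASD_DD"] == "female")
  }, numeric(1))
  # E = 4; binomial SE of the mean over 400 seeds
  se <- sqrt(23 * (4 / 23) * (19 / 23)) / sqrt(400)
  expect_lt(abs(mean(counts) - 4), 3 * se + 0.05)
})

test_that("severity scores decrease with the latent trait", {
  cfg <- default_config()
  r <- dplyr::bind_rows(lapply(1:10, function(s) sample_participants(cfg, s)))
  asd <- r[r$group != "TD", ]
  expect_lt(cor(asd$trait, asd$cars_total), -0.3)
})

test_that("simulated sessions are valid and deterministic", {
  cfg <- fast_config()
  p <- list(id = "X-01", trait = -0.5)
  s1 <- simulate_dyad_session(p, cfg, 3)
  s2 <- simulate_dyad_session(p, cfg, 3)
  expect_identical(s1$events, s2$events)
  expect_equal(nrow(validate_session(s1)), 0)
  expect_true(all(s1$events$offset <= cfg$session$duration))
})

test_that("silent and saturated dyads hit the degenerate limits", {
  cfg <- fast_config()
  cfg$behavior$cg_rate <- 0
  cfg$behavior$ch_rate <- 0
  s <- simulate_dyad_session(list(id = "s", trait = 0), cfg, 1)
  expect_equal(nrow(s$events), 0)
  ind <- score_sessions(s)
  expect_equal(ind$it, 0)
  expect_equal(ind$sic, 0)
  expect_true(is.na(ind$rsc))

  cfg2 <- fast_config()
  cfg2$behavior$ch_rate <- 0
  cfg2$behavior$resp_intercept <- 50    # p_resp ~ 1
  cfg2$behavior$engage_mean <- 1e5      # engagement outlasts the session
  s2 <- simulate_dyad_session(list(id = "t", trait = 0), cfg2, 2)
  ind2 <- score_sessions(s2)
  expect_equal(ind2$rsc, 1)
  expect_equal(ind2$cis, 0)
  expect_gt(ind2$gis, 0.9)
})

test_that("indicator means are monotone in the linked generator knobs", {
  base <- fast_config()
  mc <- function(cfg, n = 60) {
    ind <- purrr::map_dfr(seq_len(n), function(i) {
      score_sessions(simulate_dyad_session(list(id = paste0("m", i), trait = 0),
                                           cfg, seed = 1000 + i))
    })
    colMeans(ind[, c("sic", "it", "rsc", "gis", "cis")], na.rm = TRUE)
  }
  lo <- base; lo$behavior$resp_intercept <- -0.5
  hi <- base; hi$behavior$resp_intercept <- 2
  expect_lt(mc(lo)[["rsc"]], mc(hi)[["rsc"]])

  lo2 <- base; lo2$behavior$ch_rate <- 0.02
  hi2 <- base; hi2$behavior$ch_rate <- 0.25
  expect_lt(mc(lo2)[["cis"]], mc(hi2)[["cis"]])

  lo3 <- base; lo3$behavior$engage_mean <- 5
  hi3 <- base; hi3$behavior$engage_mean <- 25
  expect_lt(mc(lo3)[["it"]], mc(hi3)[["it"]])
})

test_that("simulated EEG is deterministic and artifact-free in the clean limit", {
  cfg <- fast_config(60)
  p <- list(id = "e-01", trait = 0)
  r1 <- simulate_eeg(p, cfg, 5)
  r2 <- simulate_eeg(p, cfg, 5)
  expect_identical(r1$data, r2$data)
  expect_equal(nrow(r1$data), 32)
  expect_equal(ncol(r1$data), 60 * 128)

  # noiseless single-oscillator limit: alpha dominates, theta near zero
  cfg0 <- cfg
  cfg0$eeg$background_rms <- 0
  cfg0$eeg$theta$amp <- 0
  cfg0$eeg$line_amp <- 0
  cfg0$eeg$blink_rate <- 0
  cfg0$eeg$motion_rate <- 0
  cfg0$eeg$subject_amp_sd <- 0
  rec <- simulate_eeg(p, cfg0, 6)
  psd <- compute_psd(preprocess(rec, params = list(blink_regress = FALSE)))
  # the Gaussian alpha bump leaks slightly into the 7 Hz bin, so the ratio is
  # large but finite
  expect_gt(band_power(psd, "alpha")$grand, 20 * band_power(psd, "theta")$grand)
})

test_that("alpha band power decreases with the latent trait", {
  cfg <- fast_config(60)
  cfg$eeg$blink_rate <- 0
  cfg$eeg$motion_rate <- 0
  cfg$eeg$subject_amp_sd <- 0
  mean_alpha <- function(trait, n = 12) {
    mean(vapply(seq_len(n), function(i) {
      rec <- simulate_eeg(list(id = paste0("t", trait, "-", i), trait = trait),
                          cfg, seed = 200 + i)
      band_power(compute_psd(preprocess(rec)), "alpha")$grand
    }, numeric(1)))
  }
  expect_gt(mean_alpha(-1), mean_alpha(1))
})

test_that("unknown montage errors list the available ones", {
  cfg <- default_config()
  cfg$eeg$montage <- "nope"
  expect_error(simulate_eeg(list(id = "x", trait = 0), cfg, 1),
               "unknown montage.*desk32")
})

test_that("EEG matrix + sidecar round-trips", {
  cfg <- fast_config(12)
  rec <- simulate_eeg(list(id = "rt-01", trait = 0), cfg, 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eeg(rec, f)
  rec2 <- read_eeg(f)
  expect_equal(rec2$fs, rec$fs)
  expect_equal(rec2$labels, rec$labels)
  expect_equal(rec2$data, rec$data, tolerance = 1e-10)
})

test_that("roster CSV round-trips through write_roster/read_roster", {
  cfg <- default_config()
  r <- sample_participants(cfg, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_roster(r, f)
  r2 <- read_roster(f)
  expect_equal(nrow(r2), 85)
  expect_equal(r2$fsiq, r$fsiq, tolerance = 1e-12)
  expect_false("trait" %in% names(r2))
})

test_that("config YAML round-trips and validates", {
  cfg <- default_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$behavior, cfg$behavior, tolerance = 1e-9)
  expect_equal(cfg2$groups$TD$n, 45)
})
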