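#' Compare groups with ANOVA and a sex-adjusted linear model
#'
#' For one variable across (at least two) groups: one-way ANOVA F and p; a
#' least-squares linear model `value ~ group + sex` with the reference group
#' (default `"TD"`) as baseline, whose group coefficients are the sex-adjusted
#' mean differences versus the reference with t-based p-values, Bonferroni
#' adjusted across the pairwise contrasts; plus, per contrast, the Wilcoxon
#' rank-sum p (exact for n <= 10 per group without ties, normal approximation
#' with continuity correction otherwise).
#'
#' @param data A data frame.
#' @param value,group,sex Column names (strings) of the value, group label and
#'   sex label.
#' @param ref Reference group level.
#' @param variable Optional display name for the variable.
#' @return An object of class `group_comparison`; see [tidy.group_comparison()].
#' @examples
#' d <- data.frame(y = rnorm(60), g = rep(c("TD", "A", "B"), 20),
#'                 sex = rep(c("male", "female"), 30))
#' compare_groups(d, "y", "g", "sex", ref = "TD")
#' @export
compare_groups <- function(data, value, group, sex, ref = "TD",
                           variable = value) {
  y <- data[[value]]
  g <- as.character(data[[group]])
  s <- as.character(data[[sex]])
  ok <- stats::complete.cases(y, g, s)
  y <- y[ok]; g <- g[ok]; s <- s[ok]
  tab <- table(g)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs n >= 2")
  if (stats::sd(y) == 0) stop("constant values: F undefined")
  if (!ref %in% g) ref <- names(tab)[1]
  gf <- stats::relevel(factor(g), ref = ref)

  per_group <- tibble::tibble(
    group = names(tab),
    n = as.integer(tab),
    mean = unname(vapply(names(tab), function(k) mean(y[g == k]), numeric(1))),
    se = unname(vapply(names(tab),
                       function(k) stats::sd(y[g == k]) / sqrt(sum(g == k)),
                       numeric(1)))
  )

  a <- stats::anova(stats::lm(y ~ gf))
  f_stat <- a$`F value`[1]
  f_p <- a$`Pr(>F)`[1]

  fit <- stats::lm(y ~ gf + factor(s))
  cf <- summary(fit)$coefficients
  rows <- grep("^gf", rownames(cf))
  m <- length(rows)
  contrasts <- tibble::tibble(
    group = sub("^gf", "", rownames(cf)[rows]),
    adj_diff = unname(cf[rows, "Estimate"]),
    p_raw = unname(cf[rows, "Pr(>|t|)"]),
    p_adj = unname(pmin(1, m * cf[rows, "Pr(>|t|)"]))
  )
  contrasts$p_wilcoxon <- vapply(contrasts$group, function(k) {
    suppressWarnings(stats::wilcox.test(
      y[g == k], y[g == ref],
      exact = sum(g == k) <= 10 && sum(g == ref) <= 10,
      correct = TRUE)$p.value)
  }, numeric(1))

  structure(list(
    variable = variable, ref = ref, per_group = per_group,
    f_statistic = f_stat, p_anova = f_p, contrasts = contrasts,
    n = length(y)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison %s: F = %.3f, p = %.4g; ref = %s>\n",
              x$variable, x$f_statistic, x$p_anova, x$ref))
  print(x$contrasts)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::left_join(
    dplyr::mutate(x$per_group, variable = x$variable, .before = 1),
    x$contrasts, by = "group")
}

#' @rdname compare_groups
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, statistic = x$f_statistic,
                 p.value = x$p_anova, n = x$n, ref = x$ref)
}

#' Partial Pearson correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares and correlates the residuals. The test statistic is
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` covariates, two-sided
#' p from the t distribution. With no covariates this reduces exactly to the
#' plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariates (k
#'   columns), or `NULL`.
#' @param names Optional length-2 character vector naming the pair.
#' @return An object of class `partial_corr`: list with `r`, `df`, `p`,
#'   `statistic`, `pair`, `covariates` (count).
#' @examples
#' partial_pearson(1:10, (1:10)^2, covariates = NULL)
#' @export
partial_pearson <- function(x, y, covariates = NULL, names = c("x", "y")) {
  ok <- stats::complete.cases(x, y, if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (is.null(covariates)) {
    z <- matrix(1, n, 1)
    k <- 0L
  } else {
    z <- as.matrix(covariates)
    storage.mode(z) <- "double"
    z <- z[ok, , drop = FALSE]
    k <- ncol(z)
    z <- cbind(1, z)
  }
  if (n <= 2 + k) stop("need n > 2 + number of covariates")
  if (qr(z)$rank < ncol(z)) stop("singular covariate matrix")
  rx <- stats::lm.fit(z, x)$residuals
  ry <- stats::lm.fit(z, y)$residuals
  tol0 <- 1e-10 * (stats::sd(x) + stats::sd(y) + 1)
  if (stats::sd(rx) < tol0 || stats::sd(ry) < tol0) stop("zero residual variance")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(r = r, df = df, p = p, statistic = tstat,
                 pair = names, n_covariates = k, n = n),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("<partial_corr %s ~ %s | %d covariate(s): r = %.3f, df = %d, p = %.4g>\n",
              x$pair[1], x$pair[2], x$n_covariates, x$r, x$df, x$p))
  invisible(x)
}

#' @rdname partial_pearson
#' @method tidy partial_corr
#' @export
tidy.partial_corr <- function(x, ...) {
  obj <- unclass(x)
  tibble::tibble(x = obj$pair[1], y = obj$pair[2], r = obj$r,
                 statistic = obj$statistic, df = obj$df, p.value = obj$p,
                 n_covariates = obj$n_covariates, n = obj$n)
}

#' Bonferroni adjustment
#'
#' Threshold mode (`alpha` given): the family-wise significance threshold
#' `alpha / m`. P-value mode (`p` given): `min(1, m * p)` element-wise.
#'
#' @param p Numeric vector of p-values (p-value mode), or `NULL`.
#' @param alpha Scalar significance level (threshold mode), or `NULL`.
#' @param m Family size (number of tests), >= 1.
#' @return Adjusted p-values or the adjusted threshold.
#' @examples
#' bonferroni_adjust(alpha = 0.05, m = 10) # 0.005
#' @export
bonferroni_adjust <- function(p = NULL, alpha = NULL, m) {
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1")
  if (!is.null(alpha)) return(alpha / m)
  if (is.null(p)) stop("supply p or alpha")
  pmin(1, m * p)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the full ROC curve over thresholds at midpoints between consecutive
#' sorted unique scores (plus infinities). If the raw AUC is below 0.5 the
#' scores are negated and the flip recorded, so reported AUC is always >= 0.5
#' and "high score" means "predicted positive". AUC is the trapezoidal area
#' (equal to the tie-corrected Mann-Whitney U statistic divided by n1*n2).
#' The operating cutoff maximizes the Youden index J = sensitivity +
#' specificity - 1, ties broken toward the higher specificity (the screening
#' context penalizes false positives); sensitivity, specificity and accuracy
#' ((TP+TN)/n) are reported at that cutoff. If all scores are tied the AUC is
#' 0.5 and the cutoff is flagged undefined.
#'
#' @param scores Numeric scores.
#' @param labels Binary class labels (logical, 0/1, or a factor/character with
#'   `positive` naming the positive class).
#' @param positive The positive-class label when `labels` is not logical/0-1.
#' @return An object of class `roc_result`.
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  ok <- stats::complete.cases(scores, labels)
  scores <- as.numeric(scores[ok])
  labels <- labels[ok]
  if (is.logical(labels)) {
    y <- labels
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    y <- labels == 1
  } else {
    lv <- unique(as.character(labels))
    if (is.null(positive)) {
      if (length(lv) != 2) stop("supply `positive` for non-binary labels")
      positive <- lv[2]
    }
    y <- as.character(labels) == positive
  }
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  raw <- roc_curve_points(scores, y)
  flipped <- FALSE
  sc <- scores
  curve <- raw
  if (raw$auc < 0.5) {
    sc <- -scores
    flipped <- TRUE
    curve <- roc_curve_points(sc, y)
  }
  undefined_cutoff <- length(unique(sc)) == 1
  thr <- curve$thr
  sens <- curve$sens
  spec <- curve$spec
  auc <- curve$auc

  if (undefined_cutoff) {
    cut <- NA_real_; s_at <- NA_real_; sp_at <- NA_real_; acc <- NA_real_
  } else {
    j <- sens + spec - 1
    best <- which(j == max(j))
    best <- best[which.max(spec[best])]  # tie toward higher specificity
    cut <- thr[best]
    s_at <- sens[best]; sp_at <- spec[best]
    acc <- (sum(sc[y] >= cut) + sum(sc[!y] < cut)) / (n1 + n0)
  }
  structure(list(
    auc = auc, flipped = flipped, thresholds = thr,
    sensitivity = sens, specificity = spec,
    cutoff = cut, sens_at_cutoff = s_at, spec_at_cutoff = sp_at,
    accuracy = acc, undefined_cutoff = undefined_cutoff,
    n_positive = n1, n_negative = n0
  ), class = "roc_result")
}

# full ROC curve at midpoint thresholds, AUC by trapezoidal integration
roc_curve_points <- function(sc, y) {
  us <- sort(unique(sc))
  thr <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(sc[y] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sc[!y] < t), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  list(thr = thr, sens = sens, spec = spec, auc = auc)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result: AUC = %.3f%s; Youden cutoff %.4g -> sens %.1f%%, spec %.1f%%, acc %.1f%%>\n",
    x$auc, if (x$flipped) " (scores negated)" else "",
    x$cutoff, 100 * x$sens_at_cutoff, 100 * x$spec_at_cutoff, 100 * x$accuracy))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' @rdname roc_analysis
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, flipped = x$flipped, cutoff = x$cutoff,
                 sensitivity = x$sens_at_cutoff, specificity = x$spec_at_cutoff,
                 accuracy = x$accuracy, undefined_cutoff = x$undefined_cutoff,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @rdname roc_analysis
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
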