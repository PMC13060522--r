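# Internal statistical helpers shared across stages.

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from a group center. The default
#' center is the group mean (the original Levene statistic, and the variant
#' used to gate pooled vs Welch t-tests throughout the pipeline);
#' median-centering (Brown-Forsythe) is available.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector (factor-coercible) of group labels, same length.
#' @param center `"mean"` or `"median"`.
#' @return A one-row tibble with columns `levene_F`, `levene_df1`,
#'   `levene_df2`, `levene_p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  stopifnot(nlevels(groups) >= 2)
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(values, groups, cfun)
  dev <- abs(values - centers[as.character(groups)])
  if (stats::var(dev) == 0 || all(tapply(dev, groups, stats::var) == 0)) {
    # no dispersion in the deviations: F degenerates to 0
    return(tibble::tibble(
      levene_F = 0, levene_df1 = nlevels(groups) - 1L,
      levene_df2 = length(values) - nlevels(groups), levene_p = 1
    ))
  }
  fit <- stats::anova(stats::lm(dev ~ groups))
  tibble::tibble(
    levene_F = fit$`F value`[1],
    levene_df1 = fit$Df[1],
    levene_df2 = fit$Df[2],
    levene_p = fit$`Pr(>F)`[1]
  )
}

# Cohen's d from an independent-samples t statistic:
# d = t * sqrt(1/n1 + 1/n2).
cohens_d_from_t <- function(t, n1, n2) t * sqrt(1 / n1 + 1 / n2)

# Two-group t-test with a Levene gate: pooled-variance unless Levene's
# mean-centered test rejects homogeneity at `levene_alpha`, then Welch.
# Direction convention: t > 0 <=> mean(case) > mean(control); the one-tailed
# p tests case > control.
gated_t_test <- function(control, case, levene_alpha = 0.05) {
  control <- control[!is.na(control)]
  case <- case[!is.na(case)]
  n1 <- length(control)
  n2 <- length(case)
  stopifnot(n1 >= 2, n2 >= 2)
  lev <- levene_test(
    c(control, case),
    rep(c("control", "case"), c(n1, n2))
  )
  v1 <- stats::var(control)
  v2 <- stats::var(case)
  if (v1 == 0 && v2 == 0) {
    if (mean(case) == mean(control)) {
      return(dplyr::bind_cols(
        tibble::tibble(
          t = NA_real_, df = NA_real_, p_one = NA_real_, p_two = NA_real_,
          variant = NA_character_, d = NA_real_,
          n_control = n1, n_case = n2, degenerate = TRUE
        ),
        lev
      ))
    }
    # zero variance but separated means: infinite evidence, report saturated
    tt <- list(statistic = sign(mean(case) - mean(control)) * Inf,
               parameter = n1 + n2 - 2)
    variant <- "pooled"
  } else {
    welch <- lev$levene_p < levene_alpha
    variant <- if (welch) "welch" else "pooled"
    tt <- stats::t.test(case, control, var.equal = !welch)
  }
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  p_two <- if (is.infinite(t)) 0 else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p_one <- if (is.infinite(t)) {
    if (t > 0) 0 else 1
  } else {
    stats::pt(t, df, lower.tail = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(
      t = t, df = df, p_one = p_one, p_two = p_two,
      variant = variant, d = cohens_d_from_t(t, n1, n2),
      n_control = n1, n_case = n2, degenerate = FALSE
    ),
    lev
  )
}

# Variance-ratio F test: larger sample variance over smaller, two-sided p.
variance_ratio_test <- function(control, case) {
  control <- control[!is.na(control)]
  case <- case[!is.na(case)]
  v1 <- stats::var(control)
  v2 <- stats::var(case)
  if (v1 == 0 && v2 == 0) {
    return(tibble::tibble(variance_ratio_F = NA_real_, variance_ratio_p = NA_real_))
  }
  if (v2 >= v1) {
    fstat <- v2 / v1
    df1 <- length(case) - 1L
    df2 <- length(control) - 1L
  } else {
    fstat <- v1 / v2
    df1 <- length(control) - 1L
    df2 <- length(case) - 1L
  }
  p <- min(1, 2 * stats::pf(fstat, df1, df2, lower.tail = FALSE))
  tibble::tibble(variance_ratio_F = fstat, variance_ratio_p = p)
}

# Deterministic substream seeds so that adding one modality never perturbs
# the draws of another. Offsets are fixed per stream name.
stream_seed <- function(seed, stream) {
  offsets <- c(
    expression = 101L, modules = 211L, proteins = 307L,
    pathology = 401L, covariate = 503L, pmi = 601L,
    missing = 701L, outliers = 809L
  )
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) + offsets[[stream]]) %% .Machine$integer.max
}
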