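#' Flag per-gene outliers
#'
#' Default rule: Tukey fences at 1.5 interquartile ranges beyond the
#' quartiles, computed on the supplied values (the differential-expression
#' stage applies it within each group on the analysis scale). A z-score
#' alternative (|z| > `z_cut`) is available. Vectors with fewer than three
#' non-missing values are left unscreened and the result carries
#' `attr(, "screened") = FALSE`.
#'
#' @param values Numeric vector, may contain `NA`.
#' @param rule `"tukey"` or `"zscore"`.
#' @param k Fence multiplier for the Tukey rule.
#' @param z_cut Cutoff for the z-score rule.
#' @return Logical vector, `TRUE` where a value is an outlier (`NA` stays
#'   `FALSE`), with attribute `screened`.
#' @export
#' @examples
#' screen_outliers(c(1, 1.1, 0.9, 1.05, 12))
screen_outliers <- function(values, rule = c("tukey", "zscore"),
                            k = 1.5, z_cut = 3) {
  rule <- match.arg(rule)
  mask <- rep(FALSE, length(values))
  obs <- !is.na(values)
  if (sum(obs) < 3) {
    attr(mask, "screened") <- FALSE
    return(mask)
  }
  v <- values[obs]
  if (rule == "tukey") {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- v < q[1] - k * iqr | v > q[2] + k * iqr
  } else {
    s <- stats::sd(v)
    out <- if (s == 0) rep(FALSE, length(v)) else abs(v - mean(v)) / s > z_cut
  }
  mask[obs] <- out
  attr(mask, "screened") <- TRUE
  mask
}

#' Levene-gated directional t-test for one gene
#'
#' Compares case against control expression for a single gene. By default
#' the test runs on the log2 scale (variance-stabilizing for ratio-scale
#' relative quantities); fold change is the ratio of group geometric means
#' on the linear scale. Levene's mean-centered test at p < `levene_alpha`
#' switches the pooled t-test to Welch. Cohen's d is derived as
#' \eqn{d = t\sqrt{1/n_1+1/n_2}}. One-tailed direction: case > control.
#'
#' @param control,case Positive expression values (linear scale) when
#'   `scale = "log2"`; arbitrary numeric when `scale = "linear"`.
#' @param scale Analysis scale.
#' @param levene_alpha Gate level for the Welch switch.
#' @return One-row tibble with `fc`, `log2fc`, `t`, `df`, `p_one`, `p_two`,
#'   `variant`, `d`, Levene columns and group sizes.
#' @export
gene_t_test <- function(control, case, scale = c("log2", "linear"),
                        levene_alpha = 0.05) {
  scale <- match.arg(scale)
  control <- control[!is.na(control)]
  case <- case[!is.na(case)]
  stopifnot(length(control) >= 2, length(case) >= 2)
  if (scale == "log2") {
    stopifnot(all(control > 0), all(case > 0))
    xc <- log2(control)
    xs <- log2(case)
    log2fc <- mean(xs) - mean(xc)
  } else {
    xc <- control
    xs <- case
    log2fc <- NA_real_
  }
  tt <- gated_t_test(xc, xs, levene_alpha = levene_alpha)
  fc <- if (scale == "log2") 2^log2fc else mean(xs) / mean(xc)
  dplyr::bind_cols(tibble::tibble(fc = fc, log2fc = log2fc), tt)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' capped at 1 and returned in the input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))
bh_qvalues <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1] with no missing entries", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Discovery curve over FDR thresholds
#'
#' Counts discoveries (q-values at or below threshold) along an ascending
#' grid, and locates an elbow as the grid point maximizing the discrete
#' second difference of the count curve — a documented heuristic; the
#' working threshold remains a user decision (the pipeline default is 0.2).
#'
#' @param qvals Numeric vector of q-values.
#' @param q_grid Ascending thresholds in (0, 1).
#' @return A `discovery_curve` tibble with columns `q_grid`, `discoveries`
#'   and attribute `inflection_q`.
#' @export
discovery_curve <- function(qvals, q_grid = seq(0.025, 0.5, by = 0.025)) {
  stopifnot(all(q_grid > 0), all(q_grid < 1), !is.unsorted(q_grid, strictly = TRUE))
  counts <- vapply(q_grid, function(th) sum(qvals <= th), integer(1))
  inflection <- NA_real_
  if (length(q_grid) >= 3) {
    second <- diff(counts, differences = 2)
    if (any(second != 0)) {
      inflection <- q_grid[which.max(second) + 1L]
    }
  }
  out <- tibble::tibble(q_grid = q_grid, discoveries = counts)
  attr(out, "inflection_q") <- inflection
  class(out) <- c("discovery_curve", class(out))
  out
}

#' @export
autoplot.discovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q_grid, y = .data$discoveries)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = attr(object, "inflection_q"),
                        linetype = "dashed") +
    ggplot2::labs(x = "FDR threshold (q)", y = "Discoveries",
                  title = "Discovery curve")
}

#' Per-gene differential expression over a cohort
#'
#' Applies, per gene and in order: within-group outlier screening, the
#' Levene-gated directional t-test on log2 values, fold-change and effect
#' size computation, then Benjamini-Hochberg adjustment of the selected
#' tail's p-values across genes. Genes lacking two usable values in either
#' group after screening are excluded with a reason.
#'
#' @param cohort A `cohort` object (see [simulate_cohort()] /
#'   [ingest_cohort()]) or any list with an `expression` tibble
#'   (`gene_id` + one column per case) and a `cases` tibble
#'   (`case_id`, `group`).
#' @param tail `"one"` (directed, case > control; the default) or `"two"` —
#'   which p-value feeds the FDR adjustment and sorting.
#' @param outlier_rule Passed to [screen_outliers()]; `"none"` disables
#'   screening.
#' @param q_thresholds Thresholds at which pass/fail indicator columns are
#'   added.
#' @param levene_alpha Welch gate level.
#' @return A `gene_stats` tibble, one row per tested gene, sorted by the
#'   ranking p-value, with attributes `excluded` (tibble of gene, reason)
#'   and `curve` (the [discovery_curve()] of the q-values).
#' @export
run_de <- function(cohort, tail = c("one", "two"),
                   outlier_rule = c("tukey", "zscore", "none"),
                   q_thresholds = c(0.05, 0.1, 0.2),
                   levene_alpha = 0.05) {
  tail <- match.arg(tail)
  outlier_rule <- match.arg(outlier_rule)
  expr <- cohort$expression
  cases <- cohort$cases
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr),
            is.data.frame(cases), all(c("case_id", "group") %in% names(cases)))
  check_groups(cases$group)
  ctrl_ids <- cases$case_id[cases$group == "control"]
  case_ids <- cases$case_id[cases$group == "case"]
  stopifnot(all(c(ctrl_ids, case_ids) %in% names(expr)))

  rows <- vector("list", nrow(expr))
  excluded <- list()
  for (i in seq_len(nrow(expr))) {
    gene <- expr$gene_id[i]
    vc <- as.numeric(expr[i, ctrl_ids])
    vs <- as.numeric(expr[i, case_ids])
    n_outl <- 0L
    if (outlier_rule != "none") {
      mc <- screen_outliers(log2(vc), rule = outlier_rule)
      ms <- screen_outliers(log2(vs), rule = outlier_rule)
      n_outl <- sum(mc) + sum(ms)
      vc[mc] <- NA
      vs[ms] <- NA
    }
    vc <- vc[!is.na(vc)]
    vs <- vs[!is.na(vs)]
    if (length(vc) < 2 || length(vs) < 2) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        gene_id = gene, reason = "fewer than 2 usable values in a group"
      )
      next
    }
    st <- gene_t_test(vc, vs, levene_alpha = levene_alpha)
    if (st$degenerate) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        gene_id = gene, reason = "zero variance in both groups, equal means"
      )
      next
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(gene_id = gene), st,
      tibble::tibble(n_outliers_removed = n_outl)
    )
  }
  stats_tbl <- dplyr::bind_rows(rows)
  if (nrow(stats_tbl) == 0) stop("no testable genes", call. = FALSE)
  p_rank <- if (tail == "one") stats_tbl$p_one else stats_tbl$p_two
  stats_tbl$q <- bh_qvalues(p_rank)
  for (th in q_thresholds) {
    stats_tbl[[sprintf("pass_q%g", th)]] <- stats_tbl$q <= th
  }
  stats_tbl <- dplyr::arrange(stats_tbl, if (tail == "one") .data$p_one else .data$p_two)
  attr(stats_tbl, "excluded") <- dplyr::bind_rows(excluded)
  attr(stats_tbl, "curve") <- discovery_curve(stats_tbl$q)
  attr(stats_tbl, "tail") <- tail
  class(stats_tbl) <- c("gene_stats", class(stats_tbl))
  stats_tbl
}

#' @export
glance.gene_stats <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_excluded = nrow(attr(x, "excluded") %||% tibble::tibble()),
    n_q05 = sum(x$q <= 0.05),
    n_q10 = sum(x$q <= 0.10),
    n_q20 = sum(x$q <= 0.20),
    inflection_q = attr(attr(x, "curve"), "inflection_q")
  )
}

#' @export
autoplot.gene_stats <- function(object, q_threshold = 0.2, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_one),
                 colour = .data$q <= q_threshold)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 one-tailed p",
                  colour = sprintf("q <= %.2g", q_threshold))
}
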