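#' Grouped protein-panel testing with category-wise FDR
#'
#' Applies the gene-expression statistical framework to a targeted protein
#' panel: per-target outlier screening (within group, on the log2 scale),
#' Levene-gated t-tests with Cohen's d, and Benjamini-Hochberg FDR applied
#' within each a-priori biological category (pathology, gliosis,
#' excitatory, inhibitory) rather than across the whole panel. Each target
#' additionally gets a two-sided loading-control comparison (a QC check
#' that group differences are not loading artifacts), and every target
#' whose group test is significant at `alpha` is followed up with a
#' two-model hierarchical regression adding the binary covariate.
#'
#' @param cohort A cohort object whose `proteins` tibble has columns
#'   `target`, `category`, `case_id`, `abundance`, `loading_control`, and
#'   whose `cases` tibble has `case_id`, `group`, `covariate`.
#' @param tail `"one"` (directed, case > control) or `"two"`; selects the
#'   p-value used for FDR and significance calls.
#' @param outlier_rule Passed to [screen_outliers()]; `"none"` disables.
#' @param alpha Significance level for the follow-up regressions.
#' @param unknown Unknown-covariate policy for the regressions.
#' @return A `panel_result`: list with tibbles `targets` (per-target
#'   statistics + category-wise `q`), `loading_controls`, `regressions`,
#'   and `excluded`.
#' @export
panel_tests <- function(cohort, tail = c("one", "two"),
                        outlier_rule = c("tukey", "zscore", "none"),
                        alpha = 0.05, unknown = c("absent", "drop")) {
  tail <- match.arg(tail)
  outlier_rule <- match.arg(outlier_rule)
  unknown <- match.arg(unknown)
  proteins <- cohort$proteins
  cases <- cohort$cases
  stopifnot(all(c("target", "category", "case_id", "abundance",
                  "loading_control") %in% names(proteins)))
  check_groups(cases$group)
  proteins <- dplyr::left_join(proteins,
                               cases[, c("case_id", "group", "covariate")],
                               by = "case_id")

  targets <- unique(proteins$target)
  rows <- list()
  lc_rows <- list()
  excluded <- list()
  for (tg in targets) {
    sub <- proteins[proteins$target == tg, ]
    vc <- sub$abundance[sub$group == "control"]
    vs <- sub$abundance[sub$group == "case"]
    if (outlier_rule != "none") {
      mc <- screen_outliers(log2(vc), rule = outlier_rule)
      ms <- screen_outliers(log2(vs), rule = outlier_rule)
      vc[mc] <- NA
      vs[ms] <- NA
    }
    vcc <- vc[!is.na(vc)]
    vss <- vs[!is.na(vs)]
    if (length(vcc) < 2 || length(vss) < 2) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        target = tg, reason = "fewer than 2 usable values in a group"
      )
      next
    }
    st <- gene_t_test(vcc, vss)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(target = tg, category = sub$category[1]), st
    )
    # loading-control QC runs on the untouched loading column
    lcc <- sub$loading_control[sub$group == "control"]
    lcs <- sub$loading_control[sub$group == "case"]
    lc <- gated_t_test(lcc, lcs)
    lc_rows[[length(lc_rows) + 1L]] <- tibble::tibble(
      target = tg, lc_t = lc$t, lc_df = lc$df, lc_p_two = lc$p_two
    )
  }
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) stop("no testable protein targets", call. = FALSE)
  p_sel <- if (tail == "one") tbl$p_one else tbl$p_two
  tbl$p_selected <- p_sel
  tbl$q <- NA_real_
  for (cat in unique(tbl$category)) {
    idx <- tbl$category == cat
    tbl$q[idx] <- bh_qvalues(tbl$p_selected[idx])
  }

  sig <- tbl$target[tbl$p_selected < alpha]
  reg_rows <- purrr::map_dfr(sig, function(tg) {
    sub <- proteins[proteins$target == tg, ]
    ord <- match(cases$case_id, sub$case_id)
    y <- log2(sub$abundance[ord])
    dplyr::bind_cols(
      tibble::tibble(target = tg),
      hierarchical_regression(y, cases$group, cases$covariate,
                              unknown = unknown)
    )
  })

  structure(
    list(
      targets = dplyr::arrange(tbl, .data$category, .data$p_selected),
      loading_controls = dplyr::bind_rows(lc_rows),
      regressions = reg_rows,
      excluded = dplyr::bind_rows(excluded),
      tail = tail
    ),
    class = "panel_result"
  )
}

#' @export
print.panel_result <- function(x, ...) {
  cat("<panel_result> ", nrow(x$targets), " targets tested, ",
      sum(x$targets$p_selected < 0.05), " significant at p < 0.05, ",
      nrow(x$regressions), " follow-up regression(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.panel_result <- function(x, ...) x$targets

#' @export
glance.panel_result <- function(x, ...) {
  x$targets |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      n_sig = sum(.data$p_selected < 0.05),
      n_q20 = sum(.data$q <= 0.2),
      .groups = "drop"
    )
}

#' Postmortem-interval quality control
#'
#' Correlates PMI against each pathology burden measure, the first
#' principal component of the full (group-mean-imputed) log2 gene matrix,
#' and per-case total protein abundance — all computed before any outlier
#' removal. Both the product-moment and the rank correlation are reported
#' side by side with two-sided p-values; PMI is expected to be unrelated
#' to signal, so estimates near zero support downstream analyses.
#'
#' @param cohort A cohort object with `cases` (incl. `pmi`), `pathology`,
#'   `expression`, `proteins`.
#' @return Tibble with one row per measure: `measure`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n`.
#' @export
pmi_qc <- function(cohort) {
  cases <- cohort$cases
  stopifnot("pmi" %in% names(cases))
  pmi <- cases$pmi
  if (stats::sd(pmi) == 0) {
    stop("constant PMI: correlations undefined", call. = FALSE)
  }

  measures <- list()
  path <- cohort$pathology
  if (!is.null(path)) {
    for (col in intersect(c("burden_amygdala", "burden_with_ec"),
                          names(path))) {
      measures[[col]] <- path[[col]][match(cases$case_id, path$case_id)]
    }
  }
  if (!is.null(cohort$expression)) {
    mat <- as.matrix(cohort$expression[, cases$case_id])
    rownames(mat) <- cohort$expression$gene_id
    mat <- log2(mat)
    mat <- impute_group_mean(mat, cases$group)
    keep <- apply(mat, 1, stats::sd) > 0
    pca <- fit_pca(mat[keep, , drop = FALSE], rule = "fixed", k = 1)
    measures[["expression_pc1"]] <-
      pca$scores$PC1[match(cases$case_id, pca$scores$case_id)]
  }
  if (!is.null(cohort$proteins)) {
    tot <- cohort$proteins |>
      dplyr::group_by(.data$case_id) |>
      dplyr::summarise(total = sum(.data$abundance, na.rm = TRUE),
                       .groups = "drop")
    measures[["total_protein"]] <- tot$total[match(cases$case_id,
                                                   tot$case_id)]
  }

  purrr::map_dfr(names(measures), function(nm) {
    v <- measures[[nm]]
    keep <- !is.na(v)
    pe <- stats::cor.test(pmi[keep], v[keep], method = "pearson")
    sp <- suppressWarnings(
      stats::cor.test(pmi[keep], v[keep], method = "spearman")
    )
    tibble::tibble(
      measure = nm,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      n = sum(keep)
    )
  })
}
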