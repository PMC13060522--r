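#' Ordinal tau-amyloid colocalization index
#'
#' Scores co-occurrence of two binary pathology readouts per case: 0 if
#' neither phosphorylated-tau nor beta-amyloid positivity was detected, 1 if
#' exactly one was present, 2 if both were. Vectorized.
#'
#' @param amyloid_pos,tau_pos Logical vectors of per-case positivity.
#' @return Integer vector in \{0, 1, 2\}.
#' @export
#' @examples
#' colocalization_index(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
colocalization_index <- function(amyloid_pos, tau_pos) {
  stopifnot(is.logical(amyloid_pos), is.logical(tau_pos),
            length(amyloid_pos) == length(tau_pos))
  as.integer(amyloid_pos) + as.integer(tau_pos)
}

# Tie-aware Mann-Whitney U for group x against group y:
# number of (x_i, y_j) pairs with x_i > y_j, plus half credit per tie.
mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact (or Monte-Carlo) permutation distribution of the control-group U
# under random reassignment of pooled values into groups of the observed
# sizes. Returns both per-assignment control-U and min-U.
permute_u <- function(pooled, n1, exact_cap = 1e6, mc_reps = 20000) {
  n <- length(pooled)
  n2 <- n - n1
  n_assign <- choose(n, n1)
  if (n_assign <= exact_cap) {
    idx <- utils::combn(n, n1)
    u1 <- apply(idx, 2, function(i) mw_u(pooled[i], pooled[-i]))
    method <- "exact"
  } else {
    u1 <- vapply(seq_len(mc_reps), function(r) {
      i <- sample.int(n, n1)
      mw_u(pooled[i], pooled[-i])
    }, numeric(1))
    method <- "monte-carlo"
  }
  list(u1 = u1, umin = pmin(u1, n1 * n2 - u1), method = method)
}

#' Exact Mann-Whitney comparison of ordinal group scores
#'
#' Tie-aware Mann-Whitney U test with the reported statistic taken as
#' \eqn{U = \min(U_1, U_2)} (each tied pair contributes 0.5). P-values come
#' from exhaustive enumeration of all \eqn{{n_1+n_2 \choose n_1}} group
#' assignments of the pooled values when that count is below `exact_cap`,
#' otherwise from Monte-Carlo permutation. The one-sided p targets the
#' directed hypothesis case > control; the two-sided p doubles the smaller
#' exact tail, capped at 1. Also returns the Hodges-Lehmann
#' median of pairwise case-minus-control differences with an exact-rank
#' confidence interval at the achievable level nearest the request, and the
#' rank-biserial correlation \eqn{r = 1 - 2U/(n_1 n_2)}.
#'
#' @param control,case Numeric (or ordinal-coded) vectors of scores.
#' @param confidence Requested confidence level for the Hodges-Lehmann
#'   interval; the achieved level from the exact U distribution is reported.
#' @param exact_cap Maximum number of assignments enumerated exhaustively.
#' @param mc_reps Monte-Carlo permutations used above the cap.
#' @return One-row tibble with columns `U`, `p_one`, `p_two`,
#'   `hl_estimate`, `hl_lo`, `hl_hi`, `hl_conf`, `r_rank_biserial`,
#'   `n_control`, `n_case`, `method`, `mc_se`, `degenerate`.
#' @export
#' @examples
#' index_group_test(control = c(2, 1, 1, 1), case = c(2, 2, 2, 2))
index_group_test <- function(control, case, confidence = 0.95,
                             exact_cap = 1e6, mc_reps = 20000) {
  stopifnot(length(control) >= 1, length(case) >= 1,
            !anyNA(control), !anyNA(case))
  n1 <- length(control)
  n2 <- length(case)
  pooled <- c(control, case)
  u_ctrl <- mw_u(control, case)
  u_case <- n1 * n2 - u_ctrl
  u <- min(u_ctrl, u_case)
  tol <- 1e-9

  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    p_one <- 1
    p_two <- 1
    method <- "degenerate"
    mc_se <- NA_real_
  } else {
    perm <- permute_u(pooled, n1, exact_cap = exact_cap, mc_reps = mc_reps)
    p_one <- mean(perm$u1 <= u_ctrl + tol)
    p_upper <- mean(perm$u1 >= u_ctrl - tol)
    p_two <- min(1, 2 * min(p_one, p_upper))
    method <- perm$method
    mc_se <- if (method == "monte-carlo") {
      sqrt(p_one * (1 - p_one) / length(perm$u1))
    } else NA_real_
  }

  diffs <- sort(as.vector(outer(case, control, "-")))
  hl <- stats::median(diffs)
  m <- n1 * n2
  alpha <- 1 - confidence
  # exact-rank CI from the tie-free null distribution of U
  cum <- stats::pwilcox(0:m, n1, n2)
  c_alpha <- sum(cum <= alpha / 2)  # count of u in {0,..} within the tail
  if (c_alpha == 0) {
    hl_lo <- min(diffs)
    hl_hi <- max(diffs)
    hl_conf <- 1
  } else {
    hl_lo <- diffs[c_alpha]
    hl_hi <- diffs[m - c_alpha + 1]
    hl_conf <- 1 - 2 * cum[c_alpha]
  }

  tibble::tibble(
    U = u,
    p_one = p_one,
    p_two = p_two,
    hl_estimate = hl,
    hl_lo = hl_lo,
    hl_hi = hl_hi,
    hl_conf = hl_conf,
    r_rank_biserial = 1 - 2 * u / (n1 * n2),
    n_control = n1,
    n_case = n2,
    method = method,
    mc_se = mc_se,
    degenerate = degenerate
  )
}

#' Dual-pathology contingency statistics for a 2x2 table
#'
#' Odds ratio with the Haldane-Anscombe correction applied unconditionally
#' (0.5 added to every cell) and a Woolf confidence interval on the
#' corrected cells; risk ratio by the standard Katz log-scale method on the
#' uncorrected cells; one- and two-sided Fisher exact p-values from the
#' hypergeometric distribution. Table orientation: row 1 = cases
#' (`a` dual-positive, `b` not), row 2 = controls (`c` dual-positive,
#' `d` not); OR/RR > 1 means enrichment in cases.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param confidence Confidence level for both intervals.
#' @return One-row tibble with `or_point`, `or_lo`, `or_hi`, `rr_point`,
#'   `rr_lo`, `rr_hi`, `fisher_p_one`, `fisher_p_two`, `zero_margin`.
#' @export
#' @examples
#' contingency_stats(4, 0, 1, 3)
contingency_stats <- function(a, b, c, d, confidence = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)),
            a + b > 0, c + d > 0)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  zero_margin <- (a + c) == 0 || (b + d) == 0

  # Haldane-corrected OR with Woolf CI on the corrected cells
  ah <- a + 0.5; bh <- b + 0.5; ch <- c + 0.5; dh <- d + 0.5
  or <- (ah * dh) / (bh * ch)
  se_or <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  or_ci <- exp(log(or) + c(-1, 1) * z * se_or)

  # Katz risk ratio; undefined when a group has no dual-positive reference
  if (c == 0 || a == 0) {
    rr <- if (c == 0) Inf else 0
    rr_ci <- c(NA_real_, NA_real_)
  } else {
    rr <- (a / (a + b)) / (c / (c + d))
    se_rr <- sqrt(b / (a * (a + b)) + d / (c * (c + d)))
    rr_ci <- exp(log(rr) + c(-1, 1) * z * se_rr)
  }

  # Fisher exact: margins fixed, a ~ hypergeometric
  m <- a + b   # cases
  nn <- c + d  # controls
  k <- a + c   # dual-positive margin
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  fisher_p_one <- sum(probs[support >= a])
  fisher_p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])

  tibble::tibble(
    or_point = or, or_lo = or_ci[1], or_hi = or_ci[2],
    rr_point = rr, rr_lo = rr_ci[1], rr_hi = rr_ci[2],
    fisher_p_one = fisher_p_one,
    fisher_p_two = min(1, fisher_p_two),
    zero_margin = zero_margin
  )
}

#' Levene-gated comparison of continuous pathology burden
#'
#' Independent-samples comparison of percent-positive-pixel burden (or any
#' continuous measure) between control and case groups. Levene's
#' mean-centered test at p < `levene_alpha` selects Welch's t-test,
#' otherwise the pooled-variance t-test. Reports Cohen's
#' \eqn{d = t\sqrt{1/n_1 + 1/n_2}}, a two-sided variance-ratio F test
#' (larger variance over smaller), and a tie-aware exact Mann-Whitney
#' companion. The one-tailed p targets case > control.
#'
#' @param control,case Numeric vectors (each length >= 2 after NA removal).
#' @param levene_alpha Gate level for switching to Welch.
#' @return One-row tibble combining the t-test, Levene, variance-ratio and
#'   nonparametric companion columns (`U_fallback`, `p_fallback_one`,
#'   `p_fallback_two`, `r_rank_biserial`).
#' @export
#' @examples
#' burden_compare(control = c(0.1, 0.4, 0.2, 0.5), case = c(0.9, 2.5, 1.2, 1.9))
burden_compare <- function(control, case, levene_alpha = 0.05) {
  control <- control[!is.na(control)]
  case <- case[!is.na(case)]
  stopifnot(length(control) >= 2, length(case) >= 2)
  tt <- gated_t_test(control, case, levene_alpha = levene_alpha)
  vr <- variance_ratio_test(control, case)
  np <- index_group_test(control, case)
  dplyr::bind_cols(
    tt, vr,
    tibble::tibble(
      U_fallback = np$U,
      p_fallback_one = np$p_one,
      p_fallback_two = np$p_two,
      r_rank_biserial = np$r_rank_biserial
    )
  )
}

#' Full neuropathology stage on a per-case pathology table
#'
#' Runs the ordinal colocalization-index comparison, the dual-positivity
#' contingency block, and Levene-gated burden comparisons for every burden
#' column, given a tidy per-case pathology table.
#'
#' @param pathology Data frame with columns `case_id`, `group` (values
#'   `"control"`/`"case"`), logical `amyloid_pos`, `tau_pos`, and one or
#'   more numeric burden columns (default `burden_amygdala`,
#'   `burden_with_ec`).
#' @param burden_cols Character vector of burden column names to compare.
#' @param confidence Confidence level for intervals.
#' @return An object of class `pathology_report`: a list with tibbles
#'   `index_test`, `contingency`, `burden` (one row per burden column), and
#'   the 2x2 `counts`. `tidy()` stacks everything into one long tibble.
#' @export
pathology_compare <- function(pathology,
                              burden_cols = intersect(
                                c("burden_amygdala", "burden_with_ec"),
                                names(pathology)
                              ),
                              confidence = 0.95) {
  stopifnot(is.data.frame(pathology),
            all(c("case_id", "group", "amyloid_pos", "tau_pos") %in%
                  names(pathology)))
  check_groups(pathology$group)
  pathology <- dplyr::mutate(
    pathology,
    index = colocalization_index(.data$amyloid_pos, .data$tau_pos),
    dual = .data$amyloid_pos & .data$tau_pos
  )
  ctrl <- dplyr::filter(pathology, .data$group == "control")
  cs <- dplyr::filter(pathology, .data$group == "case")

  index_test <- index_group_test(ctrl$index, cs$index,
                                 confidence = confidence)
  counts <- c(
    a = sum(cs$dual), b = sum(!cs$dual),
    c = sum(ctrl$dual), d = sum(!ctrl$dual)
  )
  contingency <- contingency_stats(unname(counts["a"]), unname(counts["b"]),
                                   unname(counts["c"]), unname(counts["d"]),
                                   confidence = confidence)
  burden <- purrr::map_dfr(burden_cols, function(col) {
    dplyr::bind_cols(
      tibble::tibble(measure = col),
      burden_compare(ctrl[[col]], cs[[col]])
    )
  })
  structure(
    list(index_test = index_test, contingency = contingency,
         burden = burden, counts = counts),
    class = "pathology_report"
  )
}

#' @export
print.pathology_report <- function(x, ...) {
  cat("<pathology_report>\n")
  cat(sprintf(
    "  colocalization index: U = %.3g, exact one-sided p = %.4f, HL = %.3g\n",
    x$index_test$U, x$index_test$p_one, x$index_test$hl_estimate
  ))
  cat(sprintf(
    "  dual positivity: OR = %.3g (%.3g-%.3g), RR = %.3g, Fisher p = %.4f\n",
    x$contingency$or_point, x$contingency$or_lo, x$contingency$or_hi,
    x$contingency$rr_point, x$contingency$fisher_p_one
  ))
  cat(sprintf("  burden measures compared: %d\n", nrow(x$burden)))
  invisible(x)
}

#' @export
tidy.pathology_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(
      tidyr::pivot_longer(x$index_test,
                          dplyr::where(is.numeric),
                          names_to = "statistic", values_to = "value"),
      block = "index", .before = 1
    )[, c("block", "statistic", "value")],
    dplyr::mutate(
      tidyr::pivot_longer(x$contingency,
                          dplyr::where(is.numeric),
                          names_to = "statistic", values_to = "value"),
      block = "contingency", .before = 1
    )[, c("block", "statistic", "value")],
    x$burden |>
      tidyr::pivot_longer(dplyr::where(is.numeric),
                          names_to = "statistic", values_to = "value") |>
      dplyr::mutate(block = paste0("burden:", .data$measure), .before = 1) |>
      dplyr::select("block", "statistic", "value")
  )
}

# shared group-label validation
check_groups <- function(group) {
  lv <- unique(as.character(group))
  if (!setequal(lv, c("control", "case"))) {
    stop("`group` must contain exactly the labels \"control\" and \"case\"; got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
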