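#' Group-mean imputation of a genes-by-cases matrix
#'
#' Replaces each missing entry with the mean of its gene's observed values
#' within the same group, leaving observed entries untouched. Every gene
#' must have at least one observed value per group.
#'
#' @param x Numeric matrix, genes in rows, cases in columns (row/col names
#'   preserved).
#' @param groups Group label per column.
#' @return Matrix of the same shape with no missing values.
#' @export
impute_group_mean <- function(x, groups) {
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  groups <- as.character(groups)
  for (g in unique(groups)) {
    cols <- which(groups == g)
    sub <- x[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    if (any(n_obs == 0)) {
      bad <- rownames(x)[n_obs == 0]
      if (is.null(bad)) bad <- which(n_obs == 0)
      stop("gene(s) fully missing in group '", g, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mu <- rowMeans(sub, na.rm = TRUE)
    for (j in cols) {
      miss <- is.na(x[, j])
      x[miss, j] <- mu[miss]
    }
  }
  x
}

#' Choose how many principal components to retain
#'
#' The scree-elbow rule retains the components before the sharpest
#' flattening of the eigenvalue profile: with eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2 \ge \dots}, the elbow index is the
#' maximizer of the discrete second difference
#' \eqn{\lambda_i - 2\lambda_{i+1} + \lambda_{i+2}} and \eqn{i + 1}
#' components are kept. Fixed-k and minimum-variance-proportion rules are
#' available. A flat (all-equal) profile has no elbow and falls back to
#' fixed-k with a warning.
#'
#' @param eigenvalues Descending numeric vector.
#' @param rule `"scree"`, `"fixed"` or `"proportion"`.
#' @param k Number of components for the fixed rule (and the flat-scree
#'   fallback).
#' @param min_prop Minimum variance proportion for the proportion rule.
#' @return Integer count of retained components (>= 1).
#' @export
#' @examples
#' retain_components(c(5.8, 1.3, 0.4, 0.3, 0.2))
retain_components <- function(eigenvalues,
                              rule = c("scree", "fixed", "proportion"),
                              k = 2, min_prop = 0.1) {
  rule <- match.arg(rule)
  m <- length(eigenvalues)
  stopifnot(m >= 1, !is.unsorted(rev(eigenvalues)))
  if (rule == "fixed") {
    if (k > m) stop("requested k = ", k, " exceeds ", m, " eigenvalues",
                    call. = FALSE)
    return(as.integer(k))
  }
  if (rule == "proportion") {
    prop <- eigenvalues / sum(eigenvalues)
    return(max(1L, sum(prop >= min_prop)))
  }
  if (m < 3 || diff(range(eigenvalues)) == 0) {
    warning("scree elbow undefined; falling back to fixed k = ", k)
    return(as.integer(min(k, m)))
  }
  second <- eigenvalues[1:(m - 2)] - 2 * eigenvalues[2:(m - 1)] +
    eigenvalues[3:m]
  as.integer(which.max(second) + 1L)
}

#' Correlation-matrix PCA with regression scores
#'
#' Eigen-decomposes the gene-gene correlation matrix of a complete
#' genes-by-cases matrix. Loadings are eigenvectors scaled by the square
#' root of their eigenvalue; per-case component scores use the regression
#' method (standardized data times the inverse correlation matrix times the
#' loadings) and are standardized to unit variance. With fewer cases than
#' genes — the expected regime — the correlation matrix is singular and the
#' Moore-Penrose pseudo-inverse is used (flagged). The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param x Numeric matrix, genes in rows, cases in columns, no missing
#'   values.
#' @param rule,k,min_prop Retention rule, passed to [retain_components()].
#' @return A `pca_model`: list with `eigenvalues`, `loadings` (tibble,
#'   gene_id + one column per component), `communalities` (over retained
#'   components), `var_explained`, `scores` (tibble, case_id + retained
#'   components), `n_retained`, `singular`.
#' @export
fit_pca <- function(x, rule = c("scree", "fixed", "proportion"),
                    k = 2, min_prop = 0.1) {
  stopifnot(is.matrix(x), !anyNA(x), nrow(x) >= 2, ncol(x) >= 2)
  rule <- match.arg(rule)
  genes <- rownames(x) %||% paste0("g", seq_len(nrow(x)))
  case_ids <- colnames(x) %||% paste0("s", seq_len(ncol(x)))
  z <- t(scale(t(x)))  # standardize each gene across cases
  if (anyNA(z)) stop("constant gene(s) cannot be standardized: ",
                     paste(genes[apply(x, 1, stats::sd) == 0], collapse = ", "),
                     call. = FALSE)
  r <- stats::cor(t(z))
  eig <- eigen(r, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  p <- length(lambda)
  loadings <- eig$vectors %*% diag(sqrt(lambda), p)

  n_ret <- retain_components(lambda, rule = rule, k = k, min_prop = min_prop)
  singular <- ncol(x) - 1 < nrow(x) || any(lambda < 1e-10)
  r_inv <- if (singular) MASS::ginv(r) else solve(r)
  weights <- r_inv %*% loadings[, seq_len(n_ret), drop = FALSE]
  scores <- t(z) %*% weights
  # unit-variance standardization + deterministic sign convention
  for (j in seq_len(n_ret)) {
    s <- stats::sd(scores[, j])
    if (s > 0) scores[, j] <- scores[, j] / s
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  comp_names <- paste0("PC", seq_len(p))
  load_tbl <- tibble::tibble(gene_id = genes)
  load_tbl[comp_names] <- as.data.frame(loadings)
  score_tbl <- tibble::tibble(case_id = case_ids)
  score_tbl[comp_names[seq_len(n_ret)]] <-
    as.data.frame(scores[, seq_len(n_ret), drop = FALSE])

  structure(
    list(
      eigenvalues = lambda,
      loadings = load_tbl,
      communalities = stats::setNames(
        rowSums(loadings[, seq_len(n_ret), drop = FALSE]^2), genes
      ),
      var_explained = lambda / sum(lambda),
      scores = score_tbl,
      n_retained = n_ret,
      singular = singular
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", nrow(x$loadings), " genes, ",
      nrow(x$scores), " cases, ", x$n_retained, " retained component(s)\n",
      sep = "")
  cat(sprintf("  variance explained (retained): %s\n",
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(x$n_retained)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"gene_id",
                      names_to = "component", values_to = "loading")
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$loadings),
    n_cases = nrow(x$scores),
    n_retained = x$n_retained,
    var_explained_retained = sum(x$var_explained[seq_len(x$n_retained)]),
    min_communality = min(x$communalities),
    singular = x$singular
  )
}

#' @export
autoplot.pca_model <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (object$n_retained >= 2) {
    if (!is.null(groups)) df$group <- groups
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
    if (!is.null(groups)) p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
    else p <- p + ggplot2::geom_point()
    p + ggplot2::labs(title = "Component scores")
  } else {
    scree <- tibble::tibble(component = seq_along(object$eigenvalues),
                            eigenvalue = object$eigenvalues)
    ggplot2::ggplot(scree, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(title = "Scree profile")
  }
}

#' Two-group MANOVA on component scores
#'
#' Wilks' \eqn{\Lambda = |W| / |T|} with the exact two-group F transform
#' \eqn{F = \frac{1-\Lambda}{\Lambda} \cdot \frac{n-p-1}{p}} on
#' \eqn{(p, n-p-1)} degrees of freedom (equivalent to Hotelling's
#' \eqn{T^2}).
#'
#' @param scores Numeric matrix or data frame, cases in rows, components in
#'   columns.
#' @param groups Two-level group label per row.
#' @return One-row tibble: `wilks_lambda`, `F`, `df1`, `df2`, `p`.
#' @export
manova_two_group <- function(scores, groups) {
  x <- as.matrix(scores)
  storage.mode(x) <- "double"
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, nrow(x) == length(groups))
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(n > p + 1)
  center <- function(m) sweep(m, 2, colMeans(m))
  tot <- crossprod(center(x))
  w <- matrix(0, p, p)
  for (g in levels(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    if (nrow(xg) < 2) stop("each group needs >= 2 cases", call. = FALSE)
    w <- w + crossprod(center(xg))
  }
  if (abs(det(w)) < 1e-12 * max(1, abs(det(tot)))) {
    stop("singular within-group covariance; MANOVA not estimable", call. = FALSE)
  }
  lambda <- det(w) / det(tot)
  f <- (1 - lambda) / lambda * (n - p - 1) / p
  tibble::tibble(
    wilks_lambda = lambda, F = f, df1 = p, df2 = n - p - 1,
    p = stats::pf(f, p, n - p - 1, lower.tail = FALSE)
  )
}

#' Eta squared from an F statistic
#'
#' \eqn{\eta^2 = F \cdot df_1 / (F \cdot df_1 + df_2)}, the proportion of
#' variance attributable to the effect in a one-way design.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Proportion in [0, 1).
#' @export
#' @examples
#' eta_squared_from_F(12.75, 1, 8)
eta_squared_from_F <- function(F, df1, df2) {
  stopifnot(F >= 0, df1 > 0, df2 > 0)
  F * df1 / (F * df1 + df2)
}

#' Two-model hierarchical regression with a binary covariate
#'
#' Ordinary least squares on standardized variables. Model 1 regresses the
#' outcome on group; Model 2 adds the covariate. The R-squared increment is
#' tested with \eqn{F_{change} = \Delta R^2 / ((1 - R^2_2)/(n-3))}.
#' Covariate entries recorded as `"unknown"` are treated as `"no"` under
#' the default policy, or dropped listwise under `"drop"`.
#'
#' @param y Numeric outcome.
#' @param group Two-level labels (`"control"`/`"case"` or any two levels;
#'   the second sorted level is coded 1).
#' @param covariate Character/factor with levels among
#'   `"yes"`, `"no"`, `"unknown"` (or logical).
#' @param unknown Policy for `"unknown"` entries.
#' @return One-row tibble: `r2_model1`, `f_model1`, `df1_m1`, `df2_m1`,
#'   `p_model1`, `beta_group_m1`, `r2_model2`, `beta_group_m2`,
#'   `beta_cov_m2`, `delta_r2`, `f_change`, `df1_change`, `df2_change`,
#'   `p_change`, `n`, `collinear`, `cov_constant`.
#' @export
hierarchical_regression <- function(y, group, covariate,
                                    unknown = c("absent", "drop")) {
  unknown <- match.arg(unknown)
  if (is.logical(covariate)) covariate <- ifelse(covariate, "yes", "no")
  covariate <- tolower(as.character(covariate))
  stopifnot(all(covariate %in% c("yes", "no", "unknown")),
            length(y) == length(group), length(y) == length(covariate))
  keep <- !is.na(y)
  if (unknown == "drop") keep <- keep & covariate != "unknown"
  y <- y[keep]
  group <- group[keep]
  covariate <- covariate[keep]
  if (unknown == "absent") covariate[covariate == "unknown"] <- "no"
  n <- length(y)
  stopifnot(n >= 4)
  g <- as.numeric(factor(group)) - 1
  if (length(unique(g)) < 2) stop("group must have both levels", call. = FALSE)
  cv <- as.numeric(covariate == "yes")

  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  zy <- zs(y); zg <- zs(g)
  cov_constant <- stats::sd(cv) == 0
  zc <- zs(cv)

  m1 <- stats::lm(zy ~ zg)
  s1 <- summary(m1)
  r2_1 <- s1$r.squared
  f1 <- unname(s1$fstatistic[1])
  p1 <- stats::pf(f1, 1, n - 2, lower.tail = FALSE)

  collinear <- !cov_constant && abs(stats::cor(zg, zc)) > 1 - 1e-10
  if (cov_constant || collinear) {
    r2_2 <- r2_1
    beta_g2 <- unname(stats::coef(m1)[2])
    beta_c2 <- NA_real_
    delta <- 0
    f_change <- 0
    p_change <- 1
  } else {
    m2 <- stats::lm(zy ~ zg + zc)
    s2 <- summary(m2)
    r2_2 <- s2$r.squared
    beta_g2 <- unname(stats::coef(m2)["zg"])
    beta_c2 <- unname(stats::coef(m2)["zc"])
    delta <- r2_2 - r2_1
    f_change <- delta / ((1 - r2_2) / (n - 3))
    p_change <- stats::pf(f_change, 1, n - 3, lower.tail = FALSE)
  }

  tibble::tibble(
    r2_model1 = r2_1, f_model1 = f1, df1_m1 = 1, df2_m1 = n - 2,
    p_model1 = p1, beta_group_m1 = unname(stats::coef(m1)[2]),
    r2_model2 = r2_2, beta_group_m2 = beta_g2, beta_cov_m2 = beta_c2,
    delta_r2 = delta, f_change = f_change,
    df1_change = 1, df2_change = n - 3, p_change = p_change,
    n = n, collinear = collinear, cov_constant = cov_constant
  )
}

#' Module-scoring stage: PCA over FDR-passing genes plus group inference
#'
#' Selects genes passing the FDR threshold from a differential-expression
#' table, imputes missing expression values with group means,
#' standardizes, fits correlation-matrix PCA, and evaluates group
#' separation: MANOVA across retained components, per-component ANOVA with
#' eta squared, and two-model hierarchical regression adding the binary
#' covariate.
#'
#' @param cohort A cohort object (expression + cases tibbles; the `cases`
#'   tibble must carry a `covariate` column).
#' @param de_table A `gene_stats` tibble from [run_de()].
#' @param q_threshold FDR threshold selecting genes for the PCA.
#' @param rule,k Component-retention rule and fixed k, passed to
#'   [fit_pca()].
#' @param unknown Unknown-covariate policy, see
#'   [hierarchical_regression()].
#' @return A `module_report`: list with the `pca_model`, `manova`
#'   (tibble), `anova` (per-component tibble with F, p, eta squared) and
#'   `regression` (per-component hierarchical-regression tibble).
#' @export
module_scores <- function(cohort, de_table, q_threshold = 0.2,
                          rule = "scree", k = 2,
                          unknown = c("absent", "drop")) {
  unknown <- match.arg(unknown)
  genes <- de_table$gene_id[de_table$q <= q_threshold]
  if (length(genes) < 2) {
    stop("fewer than 2 genes pass q <= ", q_threshold, call. = FALSE)
  }
  cases <- cohort$cases
  check_groups(cases$group)
  expr <- cohort$expression
  mat <- as.matrix(expr[match(genes, expr$gene_id), cases$case_id])
  rownames(mat) <- genes
  mat <- log2(mat)
  mat <- impute_group_mean(mat, cases$group)

  pca <- fit_pca(mat, rule = rule, k = k)
  sc <- as.matrix(pca$scores[, -1, drop = FALSE])
  man <- manova_two_group(sc, cases$group)

  anova_tbl <- purrr::map_dfr(seq_len(pca$n_retained), function(j) {
    fit <- stats::anova(stats::lm(sc[, j] ~ factor(cases$group)))
    f <- fit$`F value`[1]
    tibble::tibble(
      component = paste0("PC", j), F = f,
      df1 = fit$Df[1], df2 = fit$Df[2],
      p = fit$`Pr(>F)`[1],
      eta_squared = eta_squared_from_F(f, fit$Df[1], fit$Df[2])
    )
  })
  reg_tbl <- purrr::map_dfr(seq_len(pca$n_retained), function(j) {
    dplyr::bind_cols(
      tibble::tibble(component = paste0("PC", j)),
      hierarchical_regression(sc[, j], cases$group, cases$covariate,
                              unknown = unknown)
    )
  })
  structure(
    list(pca = pca, manova = man, anova = anova_tbl, regression = reg_tbl,
         genes = genes),
    class = "module_report"
  )
}

#' @export
print.module_report <- function(x, ...) {
  cat("<module_report> ", length(x$genes), " genes, ",
      x$pca$n_retained, " component(s)\n", sep = "")
  cat(sprintf("  MANOVA: Wilks lambda = %.4f, F(%d,%d) = %.3f, p = %.4g\n",
              x$manova$wilks_lambda, x$manova$df1, x$manova$df2,
              x$manova$F, x$manova$p))
  invisible(x)
}

#' @export
tidy.module_report <- function(x, ...) {
  dplyr::left_join(x$anova,
                   dplyr::select(x$regression, "component",
                                 "r2_model1", "delta_r2", "f_change",
                                 "p_change"),
                   by = "component")
}
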