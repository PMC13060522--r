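# All permutations of 1..n, one per row. Used for exact Spearman p-values
# at small n (n! <= 40320 for n <= 8).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman correlation with an exact permutation p-value
#'
#' Midrank Spearman correlation; the two-sided p-value is computed by
#' exhaustive permutation of one ranking when `n <= exact_n_max`
#' (default 8, i.e. at most 40320 permutations), otherwise by the
#' t-distribution approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param x,y Paired numeric vectors, `n >= 3` complete pairs.
#' @param exact_n_max Largest n for which the permutation null is
#'   enumerated.
#' @return One-row tibble: `rho`, `p_two`, `n`, `method`, `degenerate`.
#' @export
#' @examples
#' spearman_with_exact_p(1:5, c(2, 4, 5, 7, 9))
spearman_with_exact_p <- function(x, y, exact_n_max = 8) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  stopifnot(n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_two = NA_real_, n = n,
                          method = "degenerate", degenerate = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tol <- 1e-9
  if (n <= exact_n_max) {
    perms <- all_perms(n)
    rho_null <- vapply(seq_len(nrow(perms)),
                       function(i) stats::cor(rx, ry[perms[i, ]]),
                       numeric(1))
    p <- mean(abs(rho_null) >= abs(rho) - tol)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, p_two = min(1, p), n = n,
                 method = method, degenerate = FALSE)
}

#' Fisher r-to-z test for a change in correlation between groups
#'
#' \eqn{z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
#' \sqrt{v(1/(n_1-3) + 1/(n_2-3))}} with a standard-normal two-sided
#' p-value; \eqn{v = 1} by default, or 1.06 when
#' `spearman_correction = TRUE` (a variance inflation sometimes applied to
#' rank correlations). Correlations at the boundary are clamped to
#' \eqn{1 - 10^{-6}} in magnitude and flagged.
#'
#' @param r1,r2 Correlations in each group.
#' @param n1,n2 Group sample sizes (each >= 4).
#' @param spearman_correction Use the 1.06 variance factor.
#' @return One-row tibble: `z`, `p_two`, `clamped`.
#' @export
fisher_z_change <- function(r1, n1, r2, n2, spearman_correction = FALSE) {
  stopifnot(n1 >= 4, n2 >= 4)
  clamp <- function(r) sign(r) * pmin(abs(r), 1 - 1e-6)
  clamped <- abs(r1) >= 1 - 1e-6 || abs(r2) >= 1 - 1e-6
  v <- if (spearman_correction) 1.06 else 1
  z <- (atanh(clamp(r1)) - atanh(clamp(r2))) /
    sqrt(v * (1 / (n1 - 3) + 1 / (n2 - 3)))
  tibble::tibble(z = z, p_two = 2 * stats::pnorm(-abs(z)), clamped = clamped)
}

#' Within-group correlation statistics for every gene pair
#'
#' Computes, for each unordered pair of the selected genes, the Spearman
#' correlation and p-value within each group (on all available values —
#' outliers excluded from differential expression are deliberately
#' retained here to preserve variance) and the Fisher r-to-z test of the
#' between-group change. Direction labels follow the case-minus-control
#' sign of the correlation: `strengthened` when the case-group correlation
#' is larger.
#'
#' @param cohort A cohort object.
#' @param genes Genes to correlate (default: all).
#' @param exact_n_max Passed to [spearman_with_exact_p()].
#' @param spearman_correction Passed to [fisher_z_change()].
#' @return Tibble with one row per pair: `gene_a`, `gene_b`,
#'   `rho_control`, `p_control`, `n_control`, `rho_case`, `p_case`,
#'   `n_case`, `z_change`, `p_change`, `direction`.
#' @export
correlate_groups <- function(cohort, genes = NULL, exact_n_max = 8,
                             spearman_correction = FALSE) {
  expr <- cohort$expression
  cases <- cohort$cases
  check_groups(cases$group)
  if (is.null(genes)) genes <- expr$gene_id
  stopifnot(all(genes %in% expr$gene_id))
  mat <- as.matrix(expr[match(genes, expr$gene_id), cases$case_id])
  rownames(mat) <- genes
  ctrl <- mat[, cases$group == "control", drop = FALSE]
  cs <- mat[, cases$group == "case", drop = FALSE]

  pairs <- utils::combn(genes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]
    gb <- pairs[2, i]
    s1 <- spearman_with_exact_p(ctrl[ga, ], ctrl[gb, ],
                                exact_n_max = exact_n_max)
    s2 <- spearman_with_exact_p(cs[ga, ], cs[gb, ],
                                exact_n_max = exact_n_max)
    fz <- if (!s1$degenerate && !s2$degenerate &&
              s1$n >= 4 && s2$n >= 4) {
      fisher_z_change(s2$rho, s2$n, s1$rho, s1$n,
                      spearman_correction = spearman_correction)
    } else {
      tibble::tibble(z = NA_real_, p_two = NA_real_, clamped = NA)
    }
    tibble::tibble(
      gene_a = ga, gene_b = gb,
      rho_control = s1$rho, p_control = s1$p_two, n_control = s1$n,
      rho_case = s2$rho, p_case = s2$p_two, n_case = s2$n,
      z_change = fz$z, p_change = fz$p_two,
      direction = dplyr::case_when(
        is.na(fz$z) ~ NA_character_,
        fz$z >= 0 ~ "strengthened",
        TRUE ~ "weakened"
      )
    )
  })
}

canonical_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Build a differential co-expression network
#'
#' Edge set = curated interactions plus novel data-driven pairs whose
#' within-group Spearman correlation satisfies \eqn{|\rho| \ge}
#' `rho_min` with p < `p_max` in at least one group. The graph is simple
#' and undirected; curated pairs that also satisfy the rule stay a single
#' curated edge. Curated edges naming genes absent from the node set are
#' dropped with a warning (count logged on the result).
#'
#' @param pair_stats Pairwise correlation table from [correlate_groups()].
#' @param curated Optional tibble of curated edges with columns `source`,
#'   `target` (e.g. from [read_sif()]).
#' @param rho_min,p_max Novel-edge rule.
#' @param nodes Node set (default: genes appearing in `pair_stats`).
#' @return A `gene_network`: list with tibbles `nodes` and `edges`, the
#'   novel-edge rule, and `n_dropped_curated`.
#' @export
build_network <- function(pair_stats, curated = NULL,
                          rho_min = 0.9, p_max = 0.05, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(pair_stats$gene_a, pair_stats$gene_b)))
  }
  n_dropped <- 0L
  cur_keys <- character(0)
  if (!is.null(curated) && nrow(curated) > 0) {
    known <- curated$source %in% nodes & curated$target %in% nodes &
      curated$source != curated$target
    n_dropped <- sum(!known)
    if (n_dropped > 0) {
      warning(n_dropped,
              " curated edge(s) referencing unknown genes were dropped")
    }
    cur_keys <- unique(canonical_pair(curated$source[known],
                                      curated$target[known]))
  }
  ps <- dplyr::filter(pair_stats,
                      .data$gene_a %in% nodes, .data$gene_b %in% nodes)
  ps$key <- canonical_pair(ps$gene_a, ps$gene_b)
  passes <- with(ps, (!is.na(rho_control) & abs(rho_control) >= rho_min &
                        p_control < p_max) |
                   (!is.na(rho_case) & abs(rho_case) >= rho_min &
                      p_case < p_max))
  novel_keys <- setdiff(ps$key[passes], cur_keys)
  edge_keys <- c(cur_keys, novel_keys)
  edges <- ps[match(edge_keys, ps$key), ]
  # curated edges might lack correlation rows (e.g. restricted pair_stats)
  missing_cur <- is.na(edges$gene_a)
  if (any(missing_cur)) {
    parts <- strsplit(edge_keys[missing_cur], "|", fixed = TRUE)
    edges$gene_a[missing_cur] <- vapply(parts, `[`, "", 1)
    edges$gene_b[missing_cur] <- vapply(parts, `[`, "", 2)
    edges$key[missing_cur] <- edge_keys[missing_cur]
  }
  edges$source <- ifelse(edges$key %in% cur_keys, "curated", "novel")
  min_p <- pmin(edges$p_control, edges$p_case, na.rm = TRUE)
  edges$significance_class <- ifelse(!is.na(min_p) & min_p < 0.05,
                                     "solid", "dashed")
  edges <- dplyr::select(edges, -"key")
  structure(
    list(nodes = tibble::tibble(gene_id = nodes), edges = edges,
         rho_min = rho_min, p_max = p_max,
         n_dropped_curated = n_dropped),
    class = "gene_network"
  )
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = network$nodes$gene_id
  )
}

#' Topology metrics of a gene network
#'
#' Global and per-node graph statistics with the normalizations used by
#' standard network-analysis tools: betweenness normalized by
#' \eqn{(n-1)(n-2)/2}; closeness per node computed within its connected
#' component as (component size - 1) / (sum of geodesic distances); local
#' clustering as triangles over possible (0 where degree < 2);
#' characteristic path length as the mean finite pairwise distance;
#' heterogeneity as the coefficient of variation of the degree
#' distribution; degree centralization as
#' \eqn{\frac{n}{n-2}\left(\frac{k_{max}}{n-1} - density\right)}.
#' Disconnected graphs are flagged and path-based metrics are computed
#' within components.
#'
#' @param network A `gene_network` (or an igraph graph).
#' @return List with one-row tibble `global` and per-node tibble `nodes`.
#' @export
topology <- function(network) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  dens <- if (n > 1) 2 * e / (n * (n - 1)) else NA_real_
  comp <- igraph::components(g)
  dist <- igraph::distances(g)
  finite <- dist[upper.tri(dist)][is.finite(dist[upper.tri(dist)])]

  btw <- if (n > 2) igraph::betweenness(g, normalized = TRUE)
         else rep(0, n)
  # closeness within each node's component
  clo <- rep(NA_real_, n)
  for (ci in seq_len(comp$no)) {
    mem <- which(comp$membership == ci)
    if (length(mem) == 1) { clo[mem] <- 0; next }
    sub <- dist[mem, mem, drop = FALSE]
    clo[mem] <- (length(mem) - 1) / rowSums(sub)
  }
  cc_local <- unname(igraph::transitivity(g, type = "localundirected",
                                          isolates = "zero"))
  ecc <- apply(dist, 1, function(r) max(r[is.finite(r)]))
  mean_deg <- mean(deg)
  heterogeneity <- if (mean_deg > 0) {
    sqrt(mean((deg - mean_deg)^2)) / mean_deg
  } else NA_real_
  centralization <- if (n > 2) {
    n / (n - 2) * (max(deg) / (n - 1) - dens)
  } else NA_real_

  global <- tibble::tibble(
    n_nodes = n, n_edges = e,
    avg_neighbors = if (n > 0) 2 * e / n else NA_real_,
    density = dens,
    clustering_coefficient = mean(cc_local),
    char_path_length = if (length(finite)) mean(finite) else NA_real_,
    diameter = max(ecc), radius = min(ecc),
    heterogeneity = heterogeneity,
    centralization = centralization,
    n_components = comp$no,
    connected = comp$no == 1
  )
  nodes <- tibble::tibble(
    gene_id = igraph::V(g)$name,
    degree = as.numeric(deg),
    betweenness = as.numeric(btw),
    closeness = clo,
    clustering = cc_local,
    component = comp$membership
  )
  list(global = global, nodes = nodes)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$source == "curated"), " curated, ",
      sum(x$edges$source == "novel"), " novel)\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_network <- function(x, ...) x$edges

#' @export
glance.gene_network <- function(x, ...) topology(x)$global

#' @export
autoplot.gene_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  nd <- tibble::tibble(gene_id = igraph::V(g)$name,
                       x = lay[, 1], y = lay[, 2])
  ed <- dplyr::left_join(object$edges, nd,
                         by = c("gene_a" = "gene_id"))
  ed <- dplyr::left_join(ed, nd, by = c("gene_b" = "gene_id"),
                         suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_b, yend = .data$y_b,
                   linetype = .data$significance_class,
                   colour = .data$direction)
    ) +
    ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$gene_id),
                       vjust = -0.8, size = 3) +
    ggplot2::theme_void()
}

#' Annotate a network and export it for graph tools
#'
#' Attaches differential-expression, PCA and topology attributes to nodes,
#' and writes four files: a GraphML with typed node and edge attributes, a
#' SIF edge list, and node/edge attribute TSVs. The GraphML round-trips
#' through standard graph libraries.
#'
#' @param network A `gene_network`.
#' @param dir Output directory (created if needed).
#' @param de_table Optional `gene_stats` table supplying `fc` / `log2fc`
#'   per node.
#' @param pca Optional `pca_model` supplying component membership (the
#'   retained component with the largest absolute loading) and loading
#'   magnitude.
#' @param basename Stem for the output file names.
#' @return (Invisibly) a list with the annotated node tibble, the edge
#'   tibble and the written paths.
#' @export
export_network <- function(network, dir, de_table = NULL, pca = NULL,
                           basename = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- topology(network)
  nodes <- topo$nodes
  if (!is.null(de_table)) {
    nodes <- dplyr::left_join(
      nodes,
      dplyr::select(tibble::as_tibble(de_table), "gene_id", "fc", "log2fc"),
      by = "gene_id"
    )
    nodes$direction_class <- ifelse(nodes$log2fc >= 0, "up", "down")
  }
  if (!is.null(pca)) {
    k <- pca$n_retained
    lmat <- as.matrix(pca$loadings[, 1 + seq_len(k), drop = FALSE])
    rownames(lmat) <- pca$loadings$gene_id
    idx <- match(nodes$gene_id, rownames(lmat))
    comp <- apply(abs(lmat), 1, which.max)
    nodes$pca_component <- paste0("PC", comp[idx])
    nodes$loading_abs <- vapply(seq_along(idx), function(i) {
      if (is.na(idx[i])) NA_real_ else max(abs(lmat[idx[i], ]))
    }, numeric(1))
  }

  g <- as_igraph(network)
  for (col in setdiff(names(nodes), "gene_id")) {
    val <- nodes[[col]][match(igraph::V(g)$name, nodes$gene_id)]
    g <- igraph::set_vertex_attr(g, col, value = val)
  }
  edge_attrs <- setdiff(names(network$edges), c("gene_a", "gene_b"))
  for (col in edge_attrs) {
    g <- igraph::set_edge_attr(g, col, value = network$edges[[col]])
  }
  paths <- list(
    graphml = file.path(dir, paste0(basename, ".graphml")),
    sif = file.path(dir, paste0(basename, ".sif")),
    nodes = file.path(dir, paste0(basename, "_nodes.tsv")),
    edges = file.path(dir, paste0(basename, "_edges.tsv"))
  )
  igraph::write_graph(g, paths$graphml, format = "graphml")
  write_sif(
    tibble::tibble(source = network$edges$gene_a,
                   interaction = network$edges$source,
                   target = network$edges$gene_b),
    paths$sif
  )
  readr::write_tsv(nodes, paths$nodes)
  readr::write_tsv(network$edges, paths$edges)
  invisible(list(nodes = nodes, edges = network$edges, paths = paths))
}

#' Read / write simple interaction format (SIF) files
#'
#' SIF is a tab-separated edge list: source, interaction type, one or more
#' targets per line.
#'
#' @param path File path.
#' @return `read_sif()`: tibble with columns `source`, `interaction`,
#'   `target` (one row per edge).
#' @export
read_sif <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed SIF line: ", ln, call. = FALSE)
    }
    tibble::tibble(source = parts[1], interaction = parts[2],
                   target = parts[-(1:2)])
  })
}

#' @param edges Tibble with columns `source`, `interaction`, `target`.
#' @rdname read_sif
#' @export
write_sif <- function(edges, path) {
  stopifnot(all(c("source", "interaction", "target") %in% names(edges)))
  readr::write_lines(
    paste(edges$source, edges$interaction, edges$target, sep = "\t"),
    path
  )
  invisible(path)
}
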