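test_that("exact Spearman p enumerates the permutation null", {
  res <- spearman_with_exact_p(1:5, c(2, 4, 5, 7, 9))
  expect_equal(res$rho, 1)
  expect_equal(res$p_two, 2 / 120)  # only the two perfectly monotone rankings
  anti <- spearman_with_exact_p(1:5, -c(2, 4, 5, 7, 9))
  expect_equal(anti$rho, -1)
  expect_equal(anti$p_two, 2 / 120)
  const <- spearman_with_exact_p(rep(1, 5), 1:5)
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
})

test_that("exact Spearman p agrees with cor.test under no ties", {
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(7)
    y <- rnorm(7)
    got <- spearman_with_exact_p(x, y)
    want <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$rho, unname(want$estimate))
    expect_equal(got$p_two, want$p.value, tolerance = 1e-10)
  }
})

test_that("permutation p-values are calibrated under independence", {
  set.seed(15)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    spearman_with_exact_p(rnorm(6), rnorm(6))$p_two
  }, numeric(1))
  # discrete-support uniformity: rejection rate at nominal alpha close to
  # the largest achievable level below it
  expect_lt(mean(p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Fisher r-to-z change has the closed form and is antisymmetric", {
  null <- fisher_z_change(0.9, 10, 0.9, 10)
  expect_equal(null$z, 0)
  expect_equal(null$p_two, 1)
  # denominator sqrt(1/2 + 1/2) = 1 at n1 = n2 = 5
  res <- fisher_z_change(0.9, 5, -0.5, 5)
  expect_equal(res$z, atanh(0.9) - atanh(-0.5))
  expect_equal(res$z, 2.0215, tolerance = 1e-4)
  swapped <- fisher_z_change(-0.5, 5, 0.9, 5)
  expect_equal(swapped$z, -res$z)
  expect_equal(swapped$p_two, res$p_two)
  clamped <- fisher_z_change(1, 8, 0.2, 8)
  expect_true(clamped$clamped)
  expect_true(is.finite(clamped$z))
  expect_error(fisher_z_change(0.5, 3, 0.2, 8))
})

test_that("z change is zero whenever the two groups share a correlation matrix", {
  set.seed(16)
  m <- matrix(2^rnorm(4 * 10), 4, 10,
              dimnames = list(paste0("g", 1:4),
                              paste0("s", 1:10)))
  # case columns literally duplicate control columns -> identical rho
  mat <- cbind(m[, 1:5], m[, 1:5])
  colnames(mat) <- paste0("s", 1:10)
  coh <- manual_cohort(mat, rep(c("control", "case"), each = 5))
  ps <- correlate_groups(coh)
  expect_true(all(abs(ps$z_change) < 1e-10))
  expect_equal(ps$rho_control, ps$rho_case)
})

test_that("network edge set is curated union rule-passing novel pairs, deduplicated", {
  genes <- paste0("g", 1:5)
  pairs <- t(combn(genes, 2))
  ps <- tibble::tibble(
    gene_a = pairs[, 1], gene_b = pairs[, 2],
    rho_control = 0.1, p_control = 0.9, n_control = 5,
    rho_case = 0.1, p_case = 0.9, n_case = 5,
    z_change = 0, p_change = 1, direction = "strengthened"
  )
  # g1-g2 passes in control; g1-g3 passes in case; g2-g3 strong but not
  # significant; g4-g5 significant but weak
  ps$rho_control[1] <- 0.95; ps$p_control[1] <- 0.01
  ps$rho_case[2] <- -0.92; ps$p_case[2] <- 0.03
  ps$rho_control[5] <- 0.95; ps$p_control[5] <- 0.2
  ps$rho_control[10] <- 0.5; ps$p_control[10] <- 0.01
  curated <- tibble::tibble(source = c("g1", "g4"), target = c("g2", "g5"))
  net <- build_network(ps, curated = curated)
  keys <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_setequal(keys, c("g1 g2", "g4 g5", "g1 g3"))
  # curated g1-g2 stays one curated edge even though it passes the rule
  expect_equal(net$edges$source[keys == "g1 g2"], "curated")
  expect_equal(net$edges$source[keys == "g1 g3"], "novel")
  # removing the novel rule leaves exactly the curated set
  strict <- build_network(ps, curated = curated, rho_min = 1.1)
  expect_equal(sort(paste(strict$edges$gene_a, strict$edges$gene_b)),
               c("g1 g2", "g4 g5"))
  # unknown curated genes dropped with a warning
  expect_warning(
    withcur <- build_network(ps, curated = tibble::tibble(
      source = c("g1", "gX"), target = c("g2", "g3")
    )),
    "dropped"
  )
  expect_equal(withcur$n_dropped_curated, 1L)
  # empty curated set, nothing passing: edgeless graph, n components = n
  none <- build_network(dplyr::mutate(ps, rho_control = 0.1, rho_case = 0.1))
  expect_equal(nrow(none$edges), 0)
  expect_equal(topology(none)$global$n_components, 5)
})

test_that("edge significance class is solid iff min within-group p < 0.05", {
  genes <- paste0("g", 1:3)
  ps <- tibble::tibble(
    gene_a = c("g1", "g1", "g2"), gene_b = c("g2", "g3", "g3"),
    rho_control = c(0.95, 0.95, 0.95), p_control = c(0.01, 0.2, 0.9),
    n_control = 5,
    rho_case = c(0.1, 0.1, 0.95), p_case = c(0.9, 0.9, 0.04), n_case = 5,
    z_change = 1, p_change = 0.3, direction = "strengthened"
  )
  net <- build_network(ps, rho_min = 0.9, p_max = 0.5)
  cls <- setNames(net$edges$significance_class,
                  paste(net$edges$gene_a, net$edges$gene_b))
  expect_equal(unname(cls["g1 g2"]), "solid")
  expect_equal(unname(cls["g1 g3"]), "dashed")
  expect_equal(unname(cls["g2 g3"]), "solid")
})

test_that("topology metrics match brute-force oracles on random small graphs", {
  set.seed(18)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    edges <- random_graph(n)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    topo <- topology(g)
    d <- oracle_bfs_dist(n, edges)
    fin <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
    expect_equal(topo$global$char_path_length, mean(fin))
    expect_equal(topo$global$density, nrow(edges) / choose(n, 2))
    expect_equal(topo$global$avg_neighbors, 2 * nrow(edges) / n)
    ecc <- apply(d, 1, function(r) max(r[is.finite(r)]))
    expect_equal(topo$global$diameter, max(ecc))
    expect_equal(topo$global$radius, min(ecc))
    expect_equal(topo$nodes$betweenness, oracle_betweenness(n, edges),
                 tolerance = 1e-10)
    expect_equal(topo$nodes$clustering, oracle_clustering(n, edges))
    # closeness within components
    comp <- igraph::components(g)$membership
    clo <- vapply(seq_len(n), function(v) {
      mem <- which(comp == comp[v])
      if (length(mem) == 1) return(0)
      (length(mem) - 1) / sum(d[v, mem])
    }, numeric(1))
    expect_equal(topo$nodes$closeness, clo)
    # radius <= diameter <= 2 radius on connected graphs
    if (comp[1] == 1 && igraph::components(g)$no == 1) {
      expect_lte(topo$global$radius, topo$global$diameter)
      expect_lte(topo$global$diameter, 2 * topo$global$radius)
    }
  }
})

test_that("within-module correlations exceed between-module correlations", {
  genes1 <- sprintf("G%03d", 1:8)
  genes2 <- sprintf("G%03d", 9:16)
  cfg <- cohort_config(
    n_per_group = 30, n_genes = 16,
    modules = list(list(genes = genes1, loading = 0.9),
                   list(genes = genes2, loading = 0.9)),
    planted_fc = c(G001 = 1), noise_sd = 0.4,
    missing_rate = 0, outlier_rate = 0, seed = 23
  )
  coh <- simulate_cohort(cfg)
  ps <- correlate_groups(coh)
  mem <- truth_report(coh)$module_membership
  within <- !is.na(mem[ps$gene_a]) & !is.na(mem[ps$gene_b]) &
    mem[ps$gene_a] == mem[ps$gene_b]
  between <- !is.na(mem[ps$gene_a]) & !is.na(mem[ps$gene_b]) & !within
  expect_gt(mean(abs(ps$rho_control[within])),
            mean(abs(ps$rho_control[between])) + 0.3)
  wt <- wilcox.test(abs(ps$rho_control[within]),
                    abs(ps$rho_control[between]),
                    alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("GraphML export round-trips node and edge attributes", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_per_group = 5, n_genes = 8, seed = 31,
                       modules = list(
                         list(genes = sprintf("G%03d", 1:8), loading = 0.8)
                       ),
                       planted_fc = stats::setNames(rep(2, 8),
                                                    sprintf("G%03d", 1:8)),
                       missing_rate = 0, outlier_rate = 0)
  coh <- simulate_cohort(cfg)
  de <- run_de(coh)
  ps <- correlate_groups(coh)
  net <- build_network(ps, rho_min = 0.8, p_max = 0.3)
  mod <- module_scores(coh, de, q_threshold = 1, rule = "fixed", k = 2)
  out <- export_network(net, dir, de_table = de, pca = mod$pca)
  expect_true(all(file.exists(unlist(out$paths))))
  g2 <- igraph::read_graph(out$paths$graphml, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes))
  expect_equal(igraph::ecount(g2), nrow(net$edges))
  expect_setequal(igraph::V(g2)$name, net$nodes$gene_id)
  # edge attribute multiset survives the round trip
  expect_setequal(round(igraph::E(g2)$rho_control, 10),
                  round(net$edges$rho_control, 10))
  expect_setequal(igraph::E(g2)$source, net$edges$source)
  # direction_class encodes the sign of the log2 fold change
  nodes <- out$nodes
  expect_equal(nodes$direction_class,
               ifelse(nodes$log2fc >= 0, "up", "down"))
  # SIF re-import matches the edge list
  sif <- read_sif(out$paths$sif)
  expect_equal(nrow(sif), nrow(net$edges))
})
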