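# Independent brute-force oracles used to validate the package's
# statistical machinery. These deliberately take different computational
# routes than the implementation.

# Exact Mann-Whitney one/two-sided p via the rank-sum formula over all
# label assignments (implementation counts pairwise wins via outer()).
oracle_mw <- function(control, case) {
  n1 <- length(control)
  n2 <- length(case)
  pooled <- c(control, case)
  rk <- rank(pooled)
  u_from_idx <- function(i) sum(rk[i]) - n1 * (n1 + 1) / 2
  obs_u1 <- u_from_idx(seq_len(n1))
  obs_min <- min(obs_u1, n1 * n2 - obs_u1)
  idx <- utils::combn(n1 + n2, n1)
  u1 <- apply(idx, 2, u_from_idx)
  tol <- 1e-9
  p_lo <- mean(u1 <= obs_u1 + tol)
  p_hi <- mean(u1 >= obs_u1 - tol)
  list(
    U = obs_min,
    p_one = p_lo,
    p_two = min(1, 2 * min(p_lo, p_hi))
  )
}

# Benjamini-Hochberg step-up by explicit sort / cummin / unsort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hand-rolled BFS distances for a simple undirected graph given as an
# edge list over nodes 1..n.
oracle_bfs_dist <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# Betweenness by exhaustive enumeration of all simple paths per pair,
# keeping the shortest ones. Feasible for n <= 12.
oracle_betweenness <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- seen
        return()
      }
      for (w in adj[[v]]) {
        if (!(w %in% seen)) walk(w, c(seen, w))
      }
    }
    walk(s, s)
    paths
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      ns <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / ns
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Local clustering coefficient: triangles over possible neighbor pairs.
oracle_clustering <- function(n, edges) {
  amat <- matrix(0, n, n)
  for (i in seq_len(nrow(edges))) {
    amat[edges[i, 1], edges[i, 2]] <- 1
    amat[edges[i, 2], edges[i, 1]] <- 1
  }
  vapply(seq_len(n), function(v) {
    nb <- which(amat[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(amat[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))
}

# Small random simple graph as an edge matrix (guaranteed >= 1 edge).
random_graph <- function(n, p_edge = 0.35) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  pairs[keep, , drop = FALSE]
}

# Minimal cohort-shaped list for unit tests that bypass the simulator.
manual_cohort <- function(expr_mat, groups, pmi = NULL,
                          covariate = NULL) {
  ids <- colnames(expr_mat)
  if (is.null(pmi)) pmi <- seq(10, 40, length.out = length(ids))
  if (is.null(covariate)) covariate <- rep("no", length(ids))
  structure(
    list(
      cases = tibble::tibble(
        case_id = ids, group = groups,
        age = rep(72, length(ids)),
        pmi = pmi,
        covariate = covariate
      ),
      expression = dplyr::bind_cols(
        tibble::tibble(gene_id = rownames(expr_mat)),
        tibble::as_tibble(expr_mat)
      ),
      proteins = NULL, pathology = NULL, truth = NULL, config = NULL
    ),
    class = "cohort"
  )
}
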