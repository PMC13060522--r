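# Delimiter sniffing: tab wins if the header contains one, else comma.
sniff_delim <- function(path) {
  header <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", header)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  readr::read_delim(path, delim = sniff_delim(path),
                    show_col_types = FALSE, progress = FALSE)
}

#' Write a cohort to a directory of plain-text tables
#'
#' Writes `cases.tsv`, `expression.tsv` (gene_id + one column per case),
#' `pathology.tsv`, `proteins.tsv`, and — when the cohort carries planted
#' truth — a `truth.json` side-car. The layouts are exactly what
#' [ingest_cohort()] reads back.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return (Invisibly) the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$cases, file.path(dir, "cases.tsv"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$pathology, file.path(dir, "pathology.tsv"))
  readr::write_tsv(cohort$proteins, file.path(dir, "proteins.tsv"))
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(
        de_genes = tr$de_genes,
        module_membership = as.list(tr$module_membership),
        true_correlations = tr$true_correlations,
        protein_effects = as.list(tr$protein_effects)
      ),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  invisible(dir)
}

#' Read a cohort from plain-text tables
#'
#' Reads and joins the four cohort tables (TSV or CSV; the delimiter is
#' sniffed per file), validating group labels, positivity flags, burden
#' ranges, expression positivity and case-id consistency. A `truth.json`
#' side-car, if present, is restored so [truth_report()] round-trips.
#'
#' @param dir Directory containing `cases.tsv`, `expression.tsv`,
#'   `pathology.tsv`, `proteins.tsv` (or `.csv` variants); alternatively
#'   pass the four paths explicitly.
#' @param cases,expression,pathology,proteins Optional explicit paths
#'   overriding `dir`.
#' @return A `cohort` object (with `truth = NULL` unless a side-car was
#'   found).
#' @export
ingest_cohort <- function(dir = NULL, cases = NULL, expression = NULL,
                          pathology = NULL, proteins = NULL) {
  locate <- function(given, stem) {
    if (!is.null(given)) return(given)
    for (ext in c("tsv", "csv")) {
      p <- file.path(dir, paste0(stem, ".", ext))
      if (file.exists(p)) return(p)
    }
    stop("cannot locate ", stem, " table under ", dir, call. = FALSE)
  }
  cases_tbl <- read_table_auto(locate(cases, "cases"))
  expr_tbl <- read_table_auto(locate(expression, "expression"))
  path_tbl <- read_table_auto(locate(pathology, "pathology"))
  prot_tbl <- read_table_auto(locate(proteins, "proteins"))

  stopifnot(all(c("case_id", "group") %in% names(cases_tbl)),
            "gene_id" %in% names(expr_tbl))
  cases_tbl$case_id <- as.character(cases_tbl$case_id)
  check_groups(cases_tbl$group)
  ids <- cases_tbl$case_id
  if (anyDuplicated(ids)) stop("duplicate case ids", call. = FALSE)

  expr_cases <- setdiff(names(expr_tbl), "gene_id")
  orphan <- setdiff(expr_cases, ids)
  if (length(orphan)) {
    stop("case(s) present in expression but absent from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  missing_cases <- setdiff(ids, expr_cases)
  if (length(missing_cases)) {
    stop("case(s) missing from expression: ",
         paste(missing_cases, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(expr_tbl[, ids])
  if (any(vals <= 0, na.rm = TRUE)) {
    stop("expression values must be strictly positive where present",
         call. = FALSE)
  }

  stopifnot(all(c("case_id", "amyloid_pos", "tau_pos") %in% names(path_tbl)))
  path_tbl$case_id <- as.character(path_tbl$case_id)
  path_tbl$amyloid_pos <- as.logical(path_tbl$amyloid_pos)
  path_tbl$tau_pos <- as.logical(path_tbl$tau_pos)
  if (!("group" %in% names(path_tbl))) {
    path_tbl$group <- cases_tbl$group[match(path_tbl$case_id, ids)]
  }
  for (col in intersect(c("burden_amygdala", "burden_with_ec"),
                        names(path_tbl))) {
    bad <- !is.na(path_tbl[[col]]) &
      (path_tbl[[col]] < 0 | path_tbl[[col]] > 100)
    if (any(bad)) {
      stop("burden percentages out of [0,100] in `", col, "` for case(s): ",
           paste(path_tbl$case_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  orphan_p <- setdiff(path_tbl$case_id, ids)
  if (length(orphan_p)) {
    stop("pathology rows for unknown case(s): ",
         paste(orphan_p, collapse = ", "), call. = FALSE)
  }

  stopifnot(all(c("target", "category", "case_id", "abundance",
                  "loading_control") %in% names(prot_tbl)))
  prot_tbl$case_id <- as.character(prot_tbl$case_id)
  if (anyDuplicated(prot_tbl[, c("target", "case_id")])) {
    stop("duplicate (target, case) protein rows", call. = FALSE)
  }

  truth <- NULL
  if (!is.null(dir)) {
    tj <- file.path(dir, "truth.json")
    if (file.exists(tj)) {
      raw <- jsonlite::read_json(tj, simplifyVector = TRUE)
      cm <- as.matrix(raw$true_correlations)
      dimnames(cm) <- list(expr_tbl$gene_id, expr_tbl$gene_id)
      # NULL json entries (unassigned genes) must come back as NA, not drop
      membership <- vapply(raw$module_membership, function(x) {
        if (is.null(x)) NA_character_ else as.character(x)
      }, character(1))
      truth <- list(
        de_genes = tibble::as_tibble(raw$de_genes),
        module_membership = membership,
        true_correlations = cm,
        protein_effects = unlist(raw$protein_effects)
      )
    }
  }

  structure(
    list(cases = cases_tbl, expression = expr_tbl,
         proteins = tibble::as_tibble(prot_tbl),
         pathology = tibble::as_tibble(path_tbl),
         truth = truth, config = NULL),
    class = "cohort"
  )
}

#' Run the full multi-stage pipeline on a cohort
#'
#' Executes the stages in fixed order — PMI quality control first (before
#' any outlier removal), then pathology comparisons, differential
#' expression, PCA module scoring, the differential co-expression network,
#' and the protein panel — and writes every stage's outputs plus a JSON
#' run report to `out_dir`. Identical cohort and settings produce
#' byte-identical output files (stage timings are returned in R but kept
#' out of the written report for this reason).
#'
#' @param cohort A `cohort` object (from [simulate_cohort()] or
#'   [ingest_cohort()]).
#' @param out_dir Output directory.
#' @param tail Tail policy for gene and protein tests.
#' @param outlier_rule Outlier rule for the screening stages.
#' @param levene_alpha Welch gate level.
#' @param q_thresholds FDR thresholds annotated on the gene table.
#' @param q_select FDR threshold selecting genes for PCA and the network.
#' @param rho_min,p_max Novel-edge rule for the network.
#' @param retain_rule,retain_k Component retention settings.
#' @param unknown Unknown-covariate policy.
#' @param curated_sif Optional path to a curated-interaction SIF file.
#' @return A `run_report` list (also written as `report.json`).
#' @export
run_pipeline <- function(cohort, out_dir,
                         tail = "one",
                         outlier_rule = "tukey",
                         levene_alpha = 0.05,
                         q_thresholds = c(0.05, 0.1, 0.2),
                         q_select = 0.2,
                         rho_min = 0.9, p_max = 0.05,
                         retain_rule = "scree", retain_k = 2,
                         unknown = "absent",
                         curated_sif = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  qc <- clock("pmi_qc", pmi_qc(cohort))
  readr::write_tsv(qc, file.path(out_dir, "pmi_qc.tsv"))

  path_rep <- clock("pathology", pathology_compare(cohort$pathology))
  readr::write_tsv(tidy(path_rep), file.path(out_dir, "pathology.tsv"))

  de <- clock("diffexpr", run_de(
    cohort, tail = tail, outlier_rule = outlier_rule,
    q_thresholds = q_thresholds, levene_alpha = levene_alpha
  ))
  readr::write_tsv(tibble::as_tibble(de), file.path(out_dir, "gene_stats.tsv"))
  readr::write_tsv(tibble::as_tibble(attr(de, "curve")),
                   file.path(out_dir, "discovery_curve.tsv"))

  mod <- clock("modules", module_scores(
    cohort, de, q_threshold = q_select, rule = retain_rule, k = retain_k,
    unknown = unknown
  ))
  readr::write_tsv(mod$pca$loadings, file.path(out_dir, "pca_loadings.tsv"))
  readr::write_tsv(mod$pca$scores, file.path(out_dir, "pca_scores.tsv"))

  net_genes <- mod$genes
  curated <- if (!is.null(curated_sif)) read_sif(curated_sif) else NULL
  corr <- clock("correlations", correlate_groups(cohort, genes = net_genes))
  net <- build_network(corr, curated = curated,
                       rho_min = rho_min, p_max = p_max)
  topo <- topology(net)
  exp_files <- export_network(net, out_dir, de_table = de, pca = mod$pca)
  readr::write_tsv(topo$global, file.path(out_dir, "network_topology.tsv"))

  panel <- clock("proteins", panel_tests(
    cohort, tail = tail, outlier_rule = outlier_rule, unknown = unknown
  ))
  readr::write_tsv(panel$targets, file.path(out_dir, "protein_stats.tsv"))
  readr::write_tsv(panel$loading_controls,
                   file.path(out_dir, "protein_loading_controls.tsv"))
  if (nrow(panel$regressions) > 0) {
    readr::write_tsv(panel$regressions,
                     file.path(out_dir, "protein_regressions.tsv"))
  }

  report <- list(
    version = as.character(utils::packageVersion("coexdiff")),
    settings = list(
      tail = tail, outlier_rule = outlier_rule,
      levene_alpha = levene_alpha, q_thresholds = q_thresholds,
      q_select = q_select, rho_min = rho_min, p_max = p_max,
      retain_rule = retain_rule, retain_k = retain_k, unknown = unknown
    ),
    stages = list(
      pmi_qc = list(n_measures = nrow(qc)),
      pathology = list(
        n_burden_measures = nrow(path_rep$burden),
        counts = as.list(path_rep$counts)
      ),
      diffexpr = list(
        n_tested = nrow(de),
        n_excluded = nrow(attr(de, "excluded")),
        excluded = attr(de, "excluded"),
        n_pass = sum(de$q <= q_select)
      ),
      modules = list(
        n_genes = length(mod$genes),
        n_retained = mod$pca$n_retained
      ),
      network = list(
        n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
        n_curated = sum(net$edges$source == "curated"),
        n_novel = sum(net$edges$source == "novel"),
        n_dropped_curated = net$n_dropped_curated
      ),
      proteins = list(
        n_tested = nrow(panel$targets),
        n_excluded = nrow(panel$excluded),
        excluded = panel$excluded
      )
    ),
    headline = list(
      index_U = path_rep$index_test$U,
      index_p_one = path_rep$index_test$p_one,
      index_hl = path_rep$index_test$hl_estimate,
      odds_ratio = path_rep$contingency$or_point,
      risk_ratio = path_rep$contingency$rr_point,
      fisher_p_one = path_rep$contingency$fisher_p_one,
      n_de_q20 = sum(de$q <= 0.2),
      manova_wilks = mod$manova$wilks_lambda,
      manova_F = mod$manova$F,
      manova_p = mod$manova$p,
      network_density = topo$global$density,
      network_avg_neighbors = topo$global$avg_neighbors,
      network_clustering = topo$global$clustering_coefficient,
      n_protein_sig = sum(panel$targets$p_selected < 0.05)
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  report$timings <- timings
  report$results <- list(qc = qc, pathology = path_rep, de = de,
                         modules = mod, network = net, topology = topo,
                         panel = panel)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> coexdiff ", x$version, "\n", sep = "")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(s)[!vapply(s, is.data.frame, TRUE)],
                      unlist(lapply(s[!vapply(s, is.data.frame, TRUE)],
                                    paste, collapse = ",")),
                      sep = "=", collapse = "  ")))
  }
  invisible(x)
}
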