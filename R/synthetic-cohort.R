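# Default planted effects for the synthetic cohort. The 23 named genes and
# their fold changes mirror the kind of targeted AD-panel signal the
# pipeline is built for (amyloid/tau processing, lipid transport,
# inflammation, signaling), with linear fold changes spanning ~0.33-6.7x.
default_planted_fc <- function() {
  c(
    PSEN1 = 2.066, MAPT = 2.194, APP = 2.662, NCSTN = 1.681, APOE = 6.72,
    ABCA1 = 4.285, CLU = 2.352, A2M = 1.485, CTSC = 3.122, CTSD = 2.347,
    SERPINA3 = 2.74, CASP4 = 6.459, GNB2 = 2.474, GNB1 = 4.047,
    PRKCA = 1.853, PRKCZ = 1.456, PRKCG = 1.614, APBA1 = 1.818,
    NTRK2 = 1.999, HSD17B10 = 2.9, UQCRC2 = 3.507, MPO = 0.331,
    NTRK1 = 0.467
  )
}

default_protein_spec <- function() {
  tibble::tribble(
    ~target,     ~category,    ~d,
    "pTau231",   "pathology",   2.6,
    "Abeta",     "pathology",   4.6,
    "AT8",       "pathology",   0.5,
    "NeuN",      "pathology",   0.0,
    "CD68",      "gliosis",     1.6,
    "Iba1",      "gliosis",     0.0,
    "GFAP",      "gliosis",     1.0,
    "S100B",     "gliosis",     0.4,
    "Vimentin",  "gliosis",     1.4,
    "AMPAR1",    "excitatory",  2.2,
    "mGluR2_3",  "excitatory",  1.9,
    "mGluR5",    "excitatory",  1.8,
    "vGluT1",    "excitatory",  1.2,
    "NMDAR1",    "excitatory",  0.0,
    "GABABR1a",  "inhibitory", -5.0,
    "vGaT",      "inhibitory", -0.9,
    "GAD67",     "inhibitory",  1.2,
    "GABABR2",   "inhibitory",  0.0
  )
}

#' Configuration for a synthetic case-control cohort
#'
#' Defines the statistical structure of a simulated two-group molecular
#' cohort: group sizes, a latent-factor module structure for the gene
#' panel, planted fold changes, log2-normal noise, missing-value and
#' outlier injection, per-group dual-pathology probabilities, a binary
#' covariate associated with group status, postmortem-interval range, and
#' a protein panel with planted standardized effects. Defaults emulate a
#' postmortem brain-bank study: two arms of five donors, an 84-gene
#' targeted AD panel with two correlated modules and ~23 planted effects
#' (fold changes 0.33-6.7x, standardized log2 effects ~1.2-6), dual
#' pathology in all cases but a quarter of controls, and PMI drawn
#' independently of every signal.
#'
#' @param n_per_group Donors per arm (>= 2).
#' @param n_genes Genes on the panel.
#' @param modules List of module definitions, each
#'   `list(genes = <indices or names>, loading = <in [0,1]>)`; the
#'   factor-model implied correlation between two genes of one module is
#'   the product of their loadings.
#' @param planted_fc Named vector of linear fold changes (case/control).
#'   Genes absent from it have fold change 1.
#' @param noise_sd Standard deviation of log2 expression noise; the
#'   planted standardized effect of a gene is `log2(fc) / noise_sd`.
#' @param missing_rate,outlier_rate Per-entry probabilities.
#' @param outlier_magnitude Outlier offset in multiples of `noise_sd` on
#'   the log2 scale, sign drawn symmetrically.
#' @param dual_pathology_prob Named probabilities `c(control = , case = )`
#'   of dual tau-amyloid positivity.
#' @param single_pathology_prob Probability of single positivity given not
#'   dual.
#' @param covariate_group_assoc Probability that the binary covariate
#'   (TBI-like) is "yes" in cases (and "no" in controls).
#' @param unknown_rate Probability a covariate entry is recorded "unknown".
#' @param pmi_range Hours, `c(low, high)`; PMI is uniform and independent
#'   of all signal.
#' @param protein_spec Tibble with columns `target`, `category`
#'   (pathology/gliosis/excitatory/inhibitory), `d` (planted standardized
#'   log2 effect).
#' @param protein_noise_sd Log2 noise SD of protein abundances.
#' @param seed Integer master seed; per-modality substreams are derived
#'   deterministically from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 5, n_genes = 84,
                          modules = NULL,
                          planted_fc = default_planted_fc(),
                          noise_sd = 0.45,
                          missing_rate = 0.02, outlier_rate = 0.02,
                          outlier_magnitude = 4,
                          dual_pathology_prob = c(control = 0.25, case = 1),
                          single_pathology_prob = 0.5,
                          covariate_group_assoc = 0.8,
                          unknown_rate = 0.2,
                          pmi_range = c(5, 48),
                          protein_spec = default_protein_spec(),
                          protein_noise_sd = 0.5,
                          seed = 1L) {
  gene_ids <- unique(c(names(planted_fc),
                       sprintf("G%03d", seq_len(n_genes))))[seq_len(n_genes)]
  if (is.null(modules)) {
    modules <- list(
      list(genes = gene_ids[seq_len(min(14, n_genes))], loading = 0.85),
      list(genes = gene_ids[intersect(15:23, seq_len(n_genes))],
           loading = 0.85)
    )
    modules <- Filter(function(m) length(m$genes) > 0, modules)
  }
  cfg <- list(
    n_per_group = n_per_group, n_genes = n_genes, gene_ids = gene_ids,
    modules = modules, planted_fc = planted_fc, noise_sd = noise_sd,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    outlier_magnitude = outlier_magnitude,
    dual_pathology_prob = dual_pathology_prob,
    single_pathology_prob = single_pathology_prob,
    covariate_group_assoc = covariate_group_assoc,
    unknown_rate = unknown_rate,
    pmi_range = pmi_range, protein_spec = protein_spec,
    protein_noise_sd = protein_noise_sd, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  chk(cfg$n_per_group >= 2, "n_per_group", "must be >= 2")
  chk(cfg$n_genes >= 1, "n_genes", "must be positive")
  chk(all(cfg$planted_fc > 0), "planted_fc",
      "fold changes must be strictly positive")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be non-negative")
  for (p in c("missing_rate", "outlier_rate", "single_pathology_prob",
              "covariate_group_assoc", "unknown_rate")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, p, "must be a probability in [0,1]")
  }
  chk(all(cfg$dual_pathology_prob >= 0 & cfg$dual_pathology_prob <= 1) &&
        all(c("control", "case") %in% names(cfg$dual_pathology_prob)),
      "dual_pathology_prob", "needs control/case probabilities in [0,1]")
  chk(length(cfg$pmi_range) == 2 && cfg$pmi_range[1] >= 0 &&
        cfg$pmi_range[2] >= cfg$pmi_range[1], "pmi_range",
      "must be (low, high) with 0 <= low <= high")
  for (m in cfg$modules) {
    chk(all(m$genes %in% cfg$gene_ids), "modules",
        "module genes must be drawn from the gene panel")
    chk(m$loading >= 0 && m$loading <= 1, "modules",
        "loadings must lie in [0,1]")
  }
  mod_genes <- unlist(lapply(cfg$modules, `[[`, "genes"))
  chk(!anyDuplicated(mod_genes), "modules",
      "a gene may belong to at most one module")
  chk(is.data.frame(cfg$protein_spec) &&
        all(c("target", "category", "d") %in% names(cfg$protein_spec)),
      "protein_spec", "needs columns target, category, d")
  chk(all(cfg$protein_spec$category %in%
            c("pathology", "gliosis", "excitatory", "inhibitory")),
      "protein_spec", "categories must be pathology/gliosis/excitatory/inhibitory")
  invisible(cfg)
}

#' Simulate a case-control cohort with recorded ground truth
#'
#' Draws a complete multimodal cohort from a [cohort_config()]:
#' log2-normal gene expression with a latent-factor module structure and
#' planted group fold changes, missing values and symmetric outliers
#' injected at the configured rates, binary tau/amyloid pathology with
#' continuous burden, a protein panel with planted standardized effects and
#' loading-control totals, and case metadata (age, PMI independent of all
#' signal, binary covariate associated with group). Every modality draws
#' from its own deterministic substream of the master seed, so adding one
#' modality never perturbs another. The planted truth rides along for
#' downstream validation.
#'
#' @param config A `cohort_config` (or arguments forwarded to it via
#'   `...` when `config` is missing).
#' @param ... Passed to [cohort_config()] when `config` is missing.
#' @return A `cohort` object: list with tibbles `cases`, `expression`
#'   (gene_id + one column per case, linear scale, NAs for missing),
#'   `proteins` (long), `pathology`, a `truth` list, and the `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(seed = 42)
#' coh
simulate_cohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- cohort_config(...)
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n <- config$n_per_group
  case_ids <- sprintf("%s%02d", rep(c("C", "P"), each = n), c(1:n, 1:n))
  groups <- rep(c("control", "case"), each = n)
  genes <- config$gene_ids

  # --- metadata -------------------------------------------------------
  set.seed(stream_seed(config$seed, "pmi"))
  pmi <- stats::runif(2 * n, config$pmi_range[1], config$pmi_range[2])
  age <- pmax(70, round(stats::rnorm(2 * n, 72, 1.5)))
  set.seed(stream_seed(config$seed, "covariate"))
  p_yes <- ifelse(groups == "case", config$covariate_group_assoc,
                  1 - config$covariate_group_assoc)
  covariate <- ifelse(stats::runif(2 * n) < p_yes, "yes", "no")
  covariate[stats::runif(2 * n) < config$unknown_rate] <- "unknown"
  cases <- tibble::tibble(case_id = case_ids, group = groups,
                          age = age, pmi = pmi, covariate = covariate)

  # --- expression -----------------------------------------------------
  set.seed(stream_seed(config$seed, "expression"))
  loading <- stats::setNames(rep(0, length(genes)), genes)
  membership <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    loading[m$genes] <- m$loading
    membership[m$genes] <- paste0("module", i)
  }
  fc <- stats::setNames(rep(1, length(genes)), genes)
  common <- intersect(names(config$planted_fc), genes)
  fc[common] <- config$planted_fc[common]

  n_mod <- length(config$modules)
  factors <- if (n_mod > 0) {
    matrix(stats::rnorm(n_mod * 2 * n), n_mod, 2 * n)
  } else {
    matrix(0, 0, 2 * n)
  }
  log2x <- matrix(NA_real_, length(genes), 2 * n,
                  dimnames = list(genes, case_ids))
  for (g in seq_along(genes)) {
    lam <- loading[g]
    f <- if (!is.na(membership[g])) {
      factors[match(membership[g], paste0("module", seq_len(n_mod))), ]
    } else rep(0, 2 * n)
    eps <- stats::rnorm(2 * n)
    latent <- lam * f + sqrt(1 - lam^2) * eps
    shift <- ifelse(groups == "case", log2(fc[g]), 0)
    log2x[g, ] <- config$noise_sd * latent + shift
  }
  set.seed(stream_seed(config$seed, "outliers"))
  out_mask <- matrix(stats::runif(length(log2x)) < config$outlier_rate,
                     nrow(log2x))
  signs <- matrix(sample(c(-1, 1), length(log2x), replace = TRUE), nrow(log2x))
  log2x <- log2x + out_mask * signs * config$outlier_magnitude * config$noise_sd
  set.seed(stream_seed(config$seed, "missing"))
  miss_mask <- matrix(stats::runif(length(log2x)) < config$missing_rate,
                      nrow(log2x))
  expr <- 2^log2x
  expr[miss_mask] <- NA
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                                 tibble::as_tibble(expr))

  # --- pathology ------------------------------------------------------
  set.seed(stream_seed(config$seed, "pathology"))
  p_dual <- unname(config$dual_pathology_prob[groups])
  dual <- stats::runif(2 * n) < p_dual
  single <- !dual & stats::runif(2 * n) < config$single_pathology_prob
  which_single <- stats::runif(2 * n) < 0.5  # TRUE -> amyloid
  amyloid_pos <- dual | (single & which_single)
  tau_pos <- dual | (single & !which_single)
  burden <- ifelse(groups == "case",
                   abs(stats::rnorm(2 * n, 1.6, 1.2)),
                   abs(stats::rnorm(2 * n, 0.32, 0.15)))
  burden_ec <- burden + abs(stats::rnorm(2 * n, 1, 0.5))
  pathology <- tibble::tibble(
    case_id = case_ids, group = groups,
    amyloid_pos = amyloid_pos, tau_pos = tau_pos,
    burden_amygdala = pmin(100, burden),
    burden_with_ec = pmin(100, burden_ec)
  )

  # --- proteins -------------------------------------------------------
  set.seed(stream_seed(config$seed, "proteins"))
  spec <- config$protein_spec
  proteins <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    shift <- ifelse(groups == "case",
                    spec$d[i] * config$protein_noise_sd, 0)
    ab <- 2^(stats::rnorm(2 * n, 0, config$protein_noise_sd) + shift)
    tibble::tibble(
      target = spec$target[i], category = spec$category[i],
      case_id = case_ids, abundance = ab,
      loading_control = stats::rnorm(2 * n, 100, 5)
    )
  })

  truth <- list(
    de_genes = tibble::tibble(
      gene_id = names(fc)[fc != 1],
      fc = unname(fc[fc != 1]),
      d = if (config$noise_sd > 0) log2(unname(fc[fc != 1])) / config$noise_sd
          else Inf
    ),
    module_membership = membership,
    true_correlations = {
      lam <- loading
      cm <- outer(lam, lam) *
        outer(membership, membership, function(a, b) {
          !is.na(a) & !is.na(b) & a == b
        })
      diag(cm) <- 1
      dimnames(cm) <- list(genes, genes)
      cm
    },
    protein_effects = stats::setNames(spec$d, spec$target)
  )

  structure(
    list(cases = cases, expression = expression, proteins = proteins,
         pathology = pathology, truth = truth, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$cases), " cases (",
      sum(x$cases$group == "control"), " control / ",
      sum(x$cases$group == "case"), " case), ",
      nrow(x$expression), " genes, ",
      length(unique(x$proteins$target)), " protein targets\n", sep = "")
  if (is.null(x$truth)) cat("  no planted truth (ingested data)\n")
  invisible(x)
}

#' Recorded ground truth of a simulated cohort
#'
#' Returns the planted truth (differentially expressed genes with their
#' fold changes and standardized effects, module membership, implied
#' correlation matrix, protein effects). Cohorts built from user files
#' carry no truth and raise an explicit error.
#'
#' @param cohort A `cohort` object.
#' @return The truth list.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$truth)) {
    stop("no truth available: cohort was not produced by simulate_cohort()",
         call. = FALSE)
  }
  cohort$truth
}
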