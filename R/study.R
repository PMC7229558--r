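#' Simulation-study configuration
#'
#' Bundles everything one cell (or a full table) of the power study needs:
#' the generating panel, the pairing and disease models, sample sizes,
#' replication and permutation counts, the significance level, and the
#' SNP-subset scenario under which the multilocus tests see the data
#' (`"all"` columns, `"drop-causal"` — all columns except the causal one —
#' or an explicit `"subset"` of column indices). The defaults are the
#' study conditions used throughout the package's own power tables:
#' 1000 cases, 1000 controls, 500 replicates, 200 permutations for Min2,
#' alpha 0.05 and the 85\% component-selection threshold.
#'
#' @param panel a [hap_panel()].
#' @param f_st fixation parameter of the pairing law.
#' @param mode genetic mode of the causal SNP (see [disease_model()]).
#' @param theta the mode's odds ratio.
#' @param n_cases,n_controls per-replicate sample sizes.
#' @param n_reps Monte-Carlo replicates per cell.
#' @param n_perm label permutations inside each Min2 evaluation.
#' @param alpha significance level for the rejection counts.
#' @param threshold explained-variability fraction for component selection.
#' @param scenario `"all"`, `"drop-causal"`, or `"subset"`.
#' @param subset column indices when `scenario = "subset"`.
#' @param causal causal column indices to run; defaults to every
#'   polymorphic locus in turn.
#' @param seed master seed; every replicate derives its own substream from
#'   (seed, causal index, replicate index).
#' @return An object of class `study_config`.
#' @export
study_config <- function(panel, f_st = 0,
                         mode = c("additive", "dominant", "recessive", "null"),
                         theta = 1,
                         n_cases = 1000, n_controls = 1000,
                         n_reps = 500, n_perm = 200,
                         alpha = 0.05, threshold = 0.85,
                         scenario = c("all", "drop-causal", "subset"),
                         subset = NULL, causal = NULL, seed = 1) {
  stopifnot(inherits(panel, "hap_panel"))
  mode <- match.arg(mode)
  scenario <- match.arg(scenario)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_reps < 1 || n_cases < 1 || n_controls < 1 || n_perm < 1)
    stop("counts must all be >= 1")
  if (scenario == "subset") {
    if (is.null(subset) || length(subset) == 0L)
      stop("scenario 'subset' requires a nonempty subset of column indices")
    subset <- as.integer(subset)
    if (any(subset < 1L) || any(subset > panel$q) || anyDuplicated(subset))
      stop("invalid subset column indices")
  }
  if (is.null(causal)) causal <- which(!panel$monomorphic)
  causal <- as.integer(causal)
  if (any(causal < 1L) || any(causal > panel$q))
    stop("invalid causal indices")
  structure(list(panel = panel, f_st = f_st, mode = mode, theta = theta,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_reps = as.integer(n_reps), n_perm = as.integer(n_perm),
                 alpha = alpha, threshold = threshold,
                 scenario = scenario, subset = subset,
                 causal = causal, seed = as.integer(seed)),
            class = "study_config")
}

study_methods <- c("PChiP", "SSUP", "GOLD", "Min2", "PChiB")

subset_columns <- function(config, causal) {
  switch(config$scenario,
         "all" = seq_len(config$panel$q),
         "drop-causal" = setdiff(seq_len(config$panel$q), causal),
         "subset" = config$subset)
}

subset_dataset <- function(data, cols) {
  genotype_dataset(data$genotypes[, cols, drop = FALSE], data$phenotype,
                   snp_ids = data$snp_ids[cols])
}

#' Run one cell of the power study
#'
#' Simulates `n_reps` case-control datasets with the configured causal SNP,
#' applies the scenario's column subset, evaluates the requested tests, and
#' returns the fraction of replicates rejecting at `alpha`. GOLD is always
#' evaluated on the causal column of the full (unsubsetted) data — it is
#' the oracle benchmark and keeps its oracle semantics even when the
#' scenario hides the causal column from the other tests. Each replicate
#' runs under a seed derived from (master seed, causal index, replicate
#' index), so any cell is reproducible in isolation.
#'
#' @param config a [study_config()].
#' @param causal 1-based causal column index for this cell.
#' @param methods which of `"PChiP"`, `"SSUP"`, `"GOLD"`, `"Min2"`,
#'   `"PChiB"` to evaluate; all five by default.
#' @return Named numeric vector of rejection fractions (NA for methods not
#'   requested), with attributes `n_reps` and `alpha`.
#' @export
run_cell <- function(config, causal, methods = study_methods) {
  stopifnot(inherits(config, "study_config"))
  methods <- match.arg(methods, study_methods, several.ok = TRUE)
  causal <- as.integer(causal)
  if (config$panel$monomorphic[causal])
    stop("causal locus is monomorphic in the panel")
  pairing <- pairing_model(config$f_st)
  disease <- if (config$mode == "null")
    disease_model(causal, "null")
  else
    disease_model(causal, config$mode, config$theta)
  cols <- subset_columns(config, causal)
  # GOLD knows the true genetic mode; under the null it defaults to additive
  gold_coding <- if (config$mode == "null") "additive" else config$mode

  rej <- matrix(0, nrow = config$n_reps, ncol = length(study_methods),
                dimnames = list(NULL, study_methods))
  need_eb <- any(c("PChiB", "Min2") %in% methods)
  for (r in seq_len(config$n_reps)) {
    set.seed(derive_seed(config$seed, causal, r))
    data <- simulate_dataset(config$panel, pairing, disease,
                             config$n_cases, config$n_controls)
    sub <- if (identical(cols, seq_len(config$panel$q))) data
           else subset_dataset(data, cols)
    p <- c(PChiP = NA_real_, SSUP = NA_real_, GOLD = NA_real_,
           Min2 = NA_real_, PChiB = NA_real_)
    if (any(c("PChiP", "SSUP") %in% methods)) {
      sp <- prospective_score(sub)
      if ("PChiP" %in% methods)
        p[["PChiP"]] <- principal_chisq(sp, config$threshold)$p_value
      if ("SSUP" %in% methods)
        p[["SSUP"]] <- ssup_test(sp)$p_value
    }
    if ("GOLD" %in% methods)
      p[["GOLD"]] <- gold_test(data, causal, gold_coding)$p_value
    if ("Min2" %in% methods) {
      m2 <- min2_test(sub, config$threshold, config$n_perm)
      p[["Min2"]] <- m2$p_value
      p[["PChiB"]] <- m2$diagnostics$p_pchib
    } else if ("PChiB" %in% methods) {
      p[["PChiB"]] <- principal_chisq(eb_score(sub), config$threshold)$p_value
    }
    rej[r, ] <- as.numeric(p < config$alpha)
  }
  out <- colMeans(rej)
  out[setdiff(study_methods, methods)] <- NA_real_
  attr(out, "n_reps") <- config$n_reps
  attr(out, "alpha") <- config$alpha
  out
}

#' Run the full power study
#'
#' Evaluates [run_cell()] for every configured causal SNP in turn and
#' assembles the empirical rejection fractions into a power table (one row
#' per causal SNP, one column per method). When `out_dir` is given, writes
#' `power_table.tsv` and a rejection-rate plot `power_plot.pdf`.
#'
#' @param config a [study_config()].
#' @param methods methods to evaluate (see [run_cell()]).
#' @param out_dir optional output directory.
#' @return A data frame of class `power_table` with columns `causal`,
#'   the method rejection fractions, and attribute `mc_se` (per-cell
#'   Monte-Carlo standard errors `sqrt(p(1-p)/n_reps)`).
#' @export
run_study <- function(config, methods = study_methods, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  rows <- lapply(config$causal, function(ck) run_cell(config, ck, methods))
  tab <- data.frame(causal = config$causal,
                    do.call(rbind, rows), check.names = FALSE)
  attr(tab, "mc_se") <- sqrt(tab[study_methods] * (1 - tab[study_methods]) /
                               config$n_reps)
  attr(tab, "config") <- config
  class(tab) <- c("power_table", class(tab))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(out_dir, "power_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p <- plot_power_table(tab)
    ggplot2::ggsave(file.path(out_dir, "power_plot.pdf"), p,
                    width = 8, height = 5)
  }
  tab
}

#' Plot a power table
#'
#' Rejection rate of each method against the causal SNP index, one line per
#' method.
#'
#' @param tab a `power_table` from [run_study()].
#' @return A ggplot object.
#' @export
plot_power_table <- function(tab) {
  keep <- study_methods[colSums(!is.na(tab[study_methods])) > 0]
  long <- data.frame(
    causal = rep(tab$causal, length(keep)),
    method = factor(rep(keep, each = nrow(tab)), levels = study_methods),
    power = unlist(tab[keep], use.names = FALSE))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$causal, y = .data$power,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "causal SNP index", y = "empirical rejection rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Selected component counts on one null dataset
#'
#' Simulates a single null dataset under the configuration (odds ratios 1)
#' and reports how many principal components the explained-variability rule
#' selects for the additive prospective covariance (PChiP) and for the
#' codominant empirical-Bayes covariance (PChiB) — the degrees of freedom
#' the two tests absorb.
#'
#' @param config a [study_config()].
#' @param causal causal index used only to seed the replicate stream.
#' @return Named integer vector `c(s_pchip = ..., s_pchib = ...)`.
#' @export
report_absorbed_df <- function(config, causal = config$causal[[1L]]) {
  stopifnot(inherits(config, "study_config"))
  set.seed(derive_seed(config$seed, causal, 1L))
  data <- simulate_dataset(config$panel, pairing_model(config$f_st),
                           disease_model(causal, "null"),
                           config$n_cases, config$n_controls)
  tp <- principal_chisq(prospective_score(data), config$threshold)
  tb <- principal_chisq(eb_score(data), config$threshold)
  c(s_pchip = tp$diagnostics$s, s_pchib = tb$diagnostics$s)
}
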