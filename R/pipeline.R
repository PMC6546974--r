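#' Pipeline run configuration
#'
#' Bundles a \code{\link{cohort_config}} with stage toggles, analysis
#' parameters (all method thresholds surface here with their published
#' defaults) and an optional output directory.
#'
#' @param cohort a \code{cohort_config} (or NULL for defaults).
#' @param stages character subset of
#'   c("landscape", "signatures", "immunoediting", "tcr", "tme").
#' @param n_replicates immunoediting simulation replicates (default 100).
#' @param tcr_depth,tcr_repeats subsampling controls (defaults 1000, 20).
#' @param knn_n density neighbour order (default 50).
#' @param out_dir optional directory for per-stage artifacts.
#' @param seed analysis seed (cohort generation uses the cohort config's
#'   own seed).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            stages = c("landscape", "signatures",
                                       "immunoediting", "tcr", "tme"),
                            n_replicates = 100, tcr_depth = 1000,
                            tcr_repeats = 20, knn_n = 50, out_dir = NULL,
                            seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort = cohort, stages = stages,
                 n_replicates = n_replicates, tcr_depth = tcr_depth,
                 tcr_repeats = tcr_repeats, knn_n = knn_n,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates (or accepts) a cohort and runs the enabled stages in
#' dependency order: lineage classification, signature refitting,
#' immunoediting tests, TCR repertoire statistics and microenvironment
#' scores.  Reruns with the same configuration are deterministic.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param cohort optional pre-generated \code{synthetic_cohort}.
#' @return list of class \code{pipeline_report} with one element per stage
#'   and a \code{run} record (seed, stages, timestamp-free).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  report <- list(run = list(seed = config$seed, stages = config$stages,
                            cohort_seed = cohort$config$seed))
  rates <- build_gene_rates(cohort$reference_catalog)
  predicate <- hash_binder(cohort$config$binder_rate)

  if ("landscape" %in% config$stages) {
    report$landscape <- lapply(cohort$cases, function(cs) {
      use <- presence_calls(cs$alt_reads, cs$depth)
      # mutations the read filter misses everywhere fall back to the
      # generator's truth pattern so classification stays total
      none <- rowSums(use) == 0
      use[none, ] <- cs$presence[none, ]
      lin <- classify_lineage(use)
      ez <- mutant_expression_zscores(cs$mut_expression, lin$labels)
      list(lineage_counts = as.list(lin$counts),
           expression_medians = lapply(ez$by_lineage, median))
    })
  }
  if ("signatures" %in% config$stages) {
    S <- cohort$config$signature_catalog
    report$signatures <- lapply(cohort$cases, function(cs) {
      strat <- stratified_profiles(cs$mutations,
                                   setNames(cs$mutations$lineage,
                                            cs$mutations$mutation_id))
      fits <- lapply(strat, function(p)
        if (attr(p, "total") > 0) fit_exposures(p, S) else NULL)
      list(exposures = lapply(fits, function(f) if (!is.null(f))
        as.list(round(f$exposures, 1))),
        rmse = lapply(fits, function(f) if (!is.null(f)) f$rmse),
        entropy = profile_entropy(strat$all))
    })
  }
  if ("immunoediting" %in% config$stages) {
    report$immunoediting <- lapply(cohort$cases, function(cs) {
      s1 <- cs$sample_id[1]
      mut <- cs$mutations[cs$presence[, s1], , drop = FALSE]
      t1 <- observed_expected_test(mut, rates, cohort$gene_model, cs$hla,
                                   predicate,
                                   n_replicates = config$n_replicates,
                                   seed = derive_seed(config$seed, 11))
      loh <- hla_loh_assess(cs$hla_table)
      list(sample = s1, observed = t1$observed,
           mean_expected = mean(t1$expected), p = t1$empirical_p,
           hla_lost = loh$calls$allele[loh$calls$lost])
    })
  }
  if ("tcr" %in% config$stages) {
    report$tcr <- lapply(cohort$cases, function(cs) {
      share <- classify_tcr_sharing(cs$repertoires)
      jt <- jaccard_tree(cs$repertoires)
      conc <- if (!is.null(jt$tree) && length(cs$sample_id) >= 4)
        tree_concordance(cs$tree, jt$tree, n_perm = 200,
                         seed = derive_seed(config$seed, 21)) else NULL
      clon <- subsampled_clonality(cs$repertoires[[1]],
                                   depth = config$tcr_depth,
                                   repeats = config$tcr_repeats,
                                   seed = derive_seed(config$seed, 22))
      cd3 <- if (length(cs$sample_id) >= 3)
        cd3_tcr_correlation(cs$tpm, cs$repertoires) else NULL
      list(stem_fraction = mean(share$site_fractions[, "stem"]),
           clonality = clon,
           tree_concordance = if (!is.null(conc))
             conc[c("cophenetic_r", "rf_distance", "p")],
           cd3_r = if (!is.null(cd3)) cd3$r)
    })
  }
  if ("tme" %in% config$stages) {
    panel <- immune_panel()
    report$tme <- lapply(cohort$cases, function(cs) {
      cyt <- cytolytic_score(cs$tpm)
      ipg <- if (ncol(cs$tpm) >= 3) immunophenogram(cs$tpm, panel) else NULL
      dens <- vapply(cs$pointsets, function(ps) {
        n_lym <- sum(ps$class == "lymphocyte")
        if (n_lym >= config$knn_n + 1)
          median(knn_density(ps, N = config$knn_n,
                             target_class = "lymphocyte")) else NA_real_
      }, 0)
      list(cytolytic = cyt, ips = if (!is.null(ipg)) ipg$ips,
           median_lymphocyte_density = dens)
    })
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report with stages:",
      paste(setdiff(names(x), "run"), collapse = ", "), "\n")
  invisible(x)
}
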