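#' Classify mutations by metastatic lineage
#'
#' A mutation is \emph{metastatic stem} when present in all metastases of a
#' case, \emph{metastatic clade} when present in at least two but not all,
#' and \emph{metastatic private} when present in a single metastasis.
#'
#' @param presence logical (or 0/1) matrix, mutations x samples, for one
#'   case; every mutation must be present in at least one sample.
#' @return list with \code{labels} (named character vector) and
#'   \code{counts} (table over stem/clade/private).
#' @export
classify_lineage <- function(presence) {
  presence <- as.matrix(presence)
  if (ncol(presence) < 2)
    stop("lineage undefined for <2 samples")
  mode(presence) <- "logical"
  n_present <- rowSums(presence)
  if (any(n_present == 0))
    stop("every mutation must be present in at least one sample")
  labels <- ifelse(n_present == ncol(presence), "stem",
                   ifelse(n_present == 1, "private", "clade"))
  names(labels) <- rownames(presence)
  list(labels = labels,
       counts = table(factor(labels, levels = c("stem", "clade", "private"))))
}

#' Presence calls from WES read counts
#'
#' Default presence rule mirroring a per-sample WES filter: alt reads >= 3
#' and VAF >= 0.02 (both configurable).
#'
#' @param alt_reads,depth integer matrices (mutations x samples).
#' @param min_alt minimum alt reads.
#' @param min_vaf minimum variant allele fraction.
#' @return logical presence matrix.
#' @export
presence_calls <- function(alt_reads, depth, min_alt = 3, min_vaf = 0.02) {
  vaf <- ifelse(depth > 0, alt_reads / depth, 0)
  alt_reads >= min_alt & vaf >= min_vaf
}

#' Targeted-sequencing detection and sample QC
#'
#' A mutation is detected when locus coverage is at least \code{min_depth}
#' (500x), its allele fraction is at least mean + 3 SD of the control
#' allele fractions at that locus, and the allele fraction is at least 1\%.
#' A sample is flagged as failing QC when more than 90\% of its mutations
#' have AF below 5\%.
#'
#' @param sample_afs data.frame with columns \code{mutation_id}, \code{af},
#'   \code{depth} for one sample.
#' @param control_afs named list: mutation_id -> numeric vector of control
#'   allele fractions (>= 2 values per locus).
#' @param min_depth,sd_mult,min_af,qc_af,qc_frac rule parameters.
#' @return list with \code{calls} (data.frame mutation_id, detected,
#'   uncallable) and \code{sample_failed_qc} (logical).
#' @export
ts_detect <- function(sample_afs, control_afs, min_depth = 500,
                      sd_mult = 3, min_af = 0.01, qc_af = 0.05,
                      qc_frac = 0.90) {
  stopifnot(all(c("mutation_id", "af", "depth") %in% names(sample_afs)))
  detected <- logical(nrow(sample_afs))
  uncallable <- logical(nrow(sample_afs))
  for (i in seq_len(nrow(sample_afs))) {
    ctrl <- control_afs[[sample_afs$mutation_id[i]]]
    if (is.null(ctrl) || length(ctrl) < 2) {
      uncallable[i] <- TRUE
      next
    }
    thr <- mean(ctrl) + sd_mult * sd(ctrl)
    detected[i] <- sample_afs$depth[i] >= min_depth &&
      sample_afs$af[i] >= thr && sample_afs$af[i] >= min_af
  }
  callable <- !uncallable
  frac_low <- if (any(callable))
    mean(sample_afs$af[callable] < qc_af) else NA_real_
  list(calls = data.frame(mutation_id = sample_afs$mutation_id,
                          detected = detected, uncallable = uncallable,
                          stringsAsFactors = FALSE),
       sample_failed_qc = isTRUE(frac_low > qc_frac))
}

#' WES-vs-TS validation metrics
#'
#' Confusion matrix over a mutation universe: TP are calls on both
#' platforms, FP on WES only, FN on TS only, TN on neither.  Sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), precision = TP/(TP+FP), accuracy =
#' (TP+TN)/(TP+FP+FN+TN).  Undefined denominators yield \code{NaN}.
#'
#' @param wes_calls,ts_calls character vectors of called mutation ids.
#' @param universe all assessable mutation ids.
#' @return list with the four metrics and the confusion counts.
#' @export
validation_metrics <- function(wes_calls, ts_calls, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(wes_calls %in% universe) || !all(ts_calls %in% universe))
    stop("calls must be subsets of the universe")
  wes <- unique(wes_calls); ts <- unique(ts_calls)
  tp <- length(intersect(wes, ts))
  fp <- length(setdiff(wes, ts))
  fn <- length(setdiff(ts, wes))
  tn <- length(setdiff(unique(universe), union(wes, ts)))
  safe_div <- function(a, b) if (b == 0) NaN else a / b
  list(sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       precision = safe_div(tp, tp + fp),
       accuracy = safe_div(tp + tn, tp + fp + fn + tn),
       counts = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Mutant-allele expression z-scores by lineage
#'
#' Mutant-allele expression is quantified as
#' \code{log2(gene TPM x RNA VAF + 1)} and z-scored across all of a case's
#' mutations; returns the per-lineage score vectors and rank-sum
#' comparisons between lineages.  A degenerate SD of 0 (single mutation, or
#' all equal) yields z = 0.
#'
#' @param expression data.frame with columns \code{mutation_id},
#'   \code{gene_tpm}, \code{rna_vaf}.
#' @param lineage named character vector (stem/clade/private) covering the
#'   mutation ids.
#' @return list with \code{z} (named vector), \code{by_lineage} (list of
#'   vectors) and \code{tests} (pairwise Wilcoxon rank-sum p-values).
#' @export
mutant_expression_zscores <- function(expression, lineage) {
  stopifnot(all(c("mutation_id", "gene_tpm", "rna_vaf") %in%
                  names(expression)))
  if (nrow(expression) == 0) {
    warning("no expressed mutations in case")
    return(list(z = numeric(0), by_lineage = list(), tests = NULL))
  }
  val <- log2(expression$gene_tpm * expression$rna_vaf + 1)
  s <- sd(val)
  z <- if (is.na(s) || s == 0) rep(0, length(val)) else (val - mean(val)) / s
  names(z) <- expression$mutation_id
  lin <- lineage[expression$mutation_id]
  by_lineage <- split(z, factor(lin, levels = c("stem", "clade", "private")))
  pairs <- utils::combn(c("stem", "clade", "private"), 2)
  tests <- apply(pairs, 2, function(p) {
    a <- by_lineage[[p[1]]]; b <- by_lineage[[p[2]]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    suppressWarnings(wilcox.test(a, b)$p.value)
  })
  names(tests) <- apply(pairs, 2, paste, collapse = "_vs_")
  list(z = z, by_lineage = by_lineage, tests = tests)
}

#' Germline genotype concordance
#'
#' Fraction of shared germline variants between two samples; more than 90\%
#' concordance indicates related samples (same patient).  The default
#' denominator is the union (Jaccard); \code{denominator = "min"} uses the
#' smaller set.
#'
#' @param germline_a,germline_b character vectors of variant keys.
#' @param threshold relatedness threshold (strictly greater than).
#' @param denominator \code{"union"} or \code{"min"}.
#' @return list with \code{fraction_shared} and \code{related}.
#' @export
genotype_concordance <- function(germline_a, germline_b, threshold = 0.90,
                                 denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  if (length(germline_a) == 0 || length(germline_b) == 0)
    stop("germline variant sets must be non-empty")
  a <- unique(germline_a); b <- unique(germline_b)
  shared <- length(intersect(a, b))
  denom <- switch(denominator,
                  union = length(union(a, b)),
                  min = min(length(a), length(b)))
  frac <- shared / denom
  list(fraction_shared = frac, related = frac > threshold)
}

#' Binarize posterior mutation probabilities
#'
#' Rows whose posterior is below 0.5 in every sample are removed; remaining
#' entries map to 1 when p >= 0.5 and 0 otherwise (only entries strictly
#' smaller than 0.5 become 0).
#'
#' @param posterior numeric matrix in [0, 1], mutations x samples.
#' @return binary integer matrix (possibly fewer rows).
#' @export
posteriors_to_binary <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(posterior < 0 | posterior > 1, na.rm = TRUE) ||
      any(is.na(posterior)))
    stop("posterior entries must lie in [0, 1]")
  keep <- apply(posterior, 1, function(r) any(r >= 0.5))
  out <- posterior[keep, , drop = FALSE]
  mode(out) <- "numeric"
  bin <- ifelse(out >= 0.5, 1L, 0L)
  bin
}

#' Filter mutation-cluster prevalences for tree input
#'
#' Applies, in order: (1) remove clusters whose mean cellular prevalence
#' does not exceed 0.1 in any sample; (2) if several clusters are present
#' in all samples, keep only the one with the highest (overall mean)
#' prevalence; (3) call a cluster present in a sample when at least 40\% of
#' its member mutations have VAF > 0.01 there.
#'
#' @param clusters list; each element has \code{cluster_id},
#'   \code{prevalence} (named per-sample numeric) and \code{mutations}
#'   (mutation ids).
#' @param vaf numeric VAF matrix, mutations x samples.
#' @param min_prevalence,presence_frac,presence_vaf rule parameters.
#' @return list with \code{kept} (cluster ids) and \code{presence}
#'   (clusters x samples logical matrix).
#' @export
filter_prevalence_clusters <- function(clusters, vaf, min_prevalence = 0.1,
                                       presence_frac = 0.40,
                                       presence_vaf = 0.01) {
  if (length(clusters) == 0) stop("empty cluster set")
  samples <- colnames(vaf)
  prev <- t(vapply(clusters, function(cl) cl$prevalence[samples],
                   numeric(length(samples))))
  rownames(prev) <- vapply(clusters, `[[`, "", "cluster_id")
  colnames(prev) <- samples

  keep <- apply(prev, 1, function(p) any(p > min_prevalence))
  clusters <- clusters[keep]
  prev <- prev[keep, , drop = FALSE]
  if (!length(clusters)) return(list(kept = character(0), presence = NULL))

  # presence by the 40% / VAF > 0.01 rule
  pres <- t(vapply(clusters, function(cl) {
    v <- vaf[cl$mutations, , drop = FALSE]
    colMeans(v > presence_vaf) >= presence_frac
  }, logical(length(samples))))
  rownames(pres) <- rownames(prev)
  colnames(pres) <- samples

  all_sample <- which(rowSums(pres) == ncol(pres))
  if (length(all_sample) > 1) {
    best <- all_sample[which.max(rowMeans(prev[all_sample, , drop = FALSE]))]
    drop <- setdiff(all_sample, best)
    pres <- pres[-drop, , drop = FALSE]
    prev <- prev[-drop, , drop = FALSE]
  }
  list(kept = rownames(pres), presence = pres)
}
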