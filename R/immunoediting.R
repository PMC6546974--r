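#' Deterministic toy MHC-binding predicate
#'
#' Returns a predicate \code{f(peptides, alleles)} giving a surrogate IC50
#' (nM) for every (peptide, allele) pair, derived from a deterministic hash
#' so that a configurable fraction \code{rate} of random pairs falls at or
#' below 500 nM.  This is a reproducible, predictor-free surrogate used by
#' the synthetic pipeline; any function with the same signature (e.g. an
#' adapter around an external affinity predictor) can be supplied wherever
#' a binder predicate is accepted.
#'
#' @param rate fraction of (peptide, allele) pairs that bind (IC50 <= 500).
#' @return function(peptides, alleles) -> numeric IC50 vector (recycled to
#'   the longer argument).
#' @export
hash_binder <- function(rate = 0.01) {
  check_fraction(rate, "rate")
  force(rate)
  function(peptides, alleles) {
    n <- max(length(peptides), length(alleles))
    peptides <- rep_len(peptides, n)
    alleles <- rep_len(alleles, n)
    upep <- unique(peptides)
    uall <- unique(alleles)
    u <- hash_unit(upep)[match(peptides, upep)]
    ua <- hash_unit(uall)[match(alleles, uall)]
    v <- (u + ua * 0.61803398875) %% 1
    # monotone map: v in [0, rate] -> (0, 500]; above rate -> (500, 50000]
    ifelse(v <= rate, pmax(v, 1e-9) / max(rate, 1e-12) * 500,
           500 + (v - rate) / max(1 - rate, 1e-12) * 49500)
  }
}

#' Gene relative background mutation rates
#'
#' Normalises a gene-level mutation-count catalog (each gene's count
#' divided by the total) into relative rates.
#'
#' @param catalog data.frame with columns \code{gene}, \code{count}, or a
#'   named numeric vector of counts.
#' @return named numeric vector of rates summing to 1.
#' @export
build_gene_rates <- function(catalog) {
  counts <- if (is.data.frame(catalog))
    setNames(catalog$count, catalog$gene) else catalog
  if (any(counts < 0)) stop("catalog counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("catalog has no mutations")
  counts / total
}

#' Simulate a context-matched mutation set
#'
#' Every observed mutation is reassigned to a new gene drawn proportionally
#' to the gene's relative background rate (restricted to genes carrying the
#' mutation's trinucleotide context), and to a position within that gene
#' drawn proportionally to the per-base coverage weight, preserving the
#' substitution and trinucleotide context (up to strand).  The simulated
#' set has exactly the observed context multiset.
#'
#' @param observed data.frame with \code{ref}, \code{alt}, \code{context}.
#' @param rates named gene rates (see \code{\link{build_gene_rates}}).
#' @param gene_model gene model from a \code{\link{generate_cohort}} object
#'   (coding sequences, coverage weights, context index).
#' @param seed integer seed.
#' @return data.frame like \code{observed} with new \code{gene},
#'   \code{pos}, \code{ref}, \code{alt}, \code{context}, protein annotation
#'   columns and the originating \code{channel}.
#' @export
simulate_mutation_set <- function(observed, rates, gene_model, seed = 1,
                                  placer = NULL) {
  ch <- channel_of(observed$ref, observed$alt, observed$context)
  if (any(is.na(ch)))
    stop("observed mutations contain invalid substitutions/contexts")
  parts <- channel_parts(ch)
  if (is.null(placer)) placer <- context_placer(gene_model, rates)
  with_seed(seed, {
    placed <- placer(parts$context)
    ann <- annotate_placed(placed, parts, gene_model)
    ann$channel <- ch
    ann
  })
}

#' Enumerate candidate neo-epitope 9-mers for a missense mutation
#'
#' The mutant protein is windowed to \code{window} residues with the mutant
#' amino acid central (truncated at the protein ends) and every 9-mer
#' containing the mutant position is emitted, paired with the
#' corresponding wild-type 9-mer.
#'
#' @param protein wild-type amino-acid sequence (single string).
#' @param aa_pos 1-based mutated residue position.
#' @param aa_alt mutant amino acid.
#' @param window odd window width between 17 and 21.
#' @return data.frame with columns \code{mutant}, \code{wildtype},
#'   \code{start} (position of the 9-mer in the protein).
#' @export
enumerate_candidate_peptides <- function(protein, aa_pos, aa_alt,
                                         window = 17) {
  L <- nchar(protein)
  if (L < 9) stop("protein shorter than 9 residues")
  if (aa_pos < 1 || aa_pos > L) stop("aa_pos outside the protein")
  if (!window %in% c(17, 19, 21)) stop("window must be 17, 19 or 21")
  if (aa_alt == "*" || substr(protein, aa_pos, aa_pos) == aa_alt)
    stop("candidate peptides are defined for missense mutations only")
  flank <- (window - 1) / 2
  lo <- max(1, aa_pos - flank)
  hi <- min(L, aa_pos + flank)
  mut <- protein
  substr(mut, aa_pos, aa_pos) <- aa_alt
  starts <- seq(max(lo, aa_pos - 8), min(aa_pos, hi - 8))
  starts <- starts[starts >= 1 & starts + 8 <= L]
  data.frame(mutant = substring(mut, starts, starts + 8),
             wildtype = substring(protein, starts, starts + 8),
             start = starts, stringsAsFactors = FALSE)
}

# Do any of the mutations' mutant 9-mers bind any allele?  Vectorised over
# the whole mutation table: the mutant window is built per mutation, every
# 9-mer covering the mutant residue is crossed with the allele set, and one
# predicate call scores all pairs.  Equivalent to looping
# enumerate_candidate_peptides() per mutation (property-tested).
mutations_bind_any <- function(mutations, gene_model, alleles, predicate,
                               ic50_threshold = 500, window = 17) {
  n <- nrow(mutations)
  out <- logical(n)
  mis <- which(mutations$effect == "missense")
  if (!length(mis)) return(out)
  prot <- unname(gene_model$protein[mutations$gene[mis]])
  L <- nchar(prot)
  pos <- mutations$aa_pos[mis]
  flank <- (window - 1) / 2
  lo <- pmax(1, pos - flank)
  hi <- pmin(L, pos + flank)
  win <- substr(prot, lo, hi)
  mpos <- pos - lo + 1
  substr(win, mpos, mpos) <- mutations$aa_alt[mis]
  wlen <- nchar(win)
  s_lo <- pmax(1, mpos - 8)
  s_hi <- pmin(mpos, wlen - 8)
  ok <- wlen >= 9 & s_hi >= s_lo
  counts <- ifelse(ok, s_hi - s_lo + 1, 0L)
  idx <- rep(seq_along(mis), counts)
  starts <- unlist(lapply(which(ok), function(i) s_lo[i]:s_hi[i]),
                   use.names = FALSE)
  if (!length(starts)) return(out)
  peps <- substr(win[idx], starts, starts + 8)
  np <- length(peps)
  ic50 <- predicate(rep(peps, times = length(alleles)),
                    rep(alleles, each = np))
  hit <- rep(idx, times = length(alleles))[ic50 <= ic50_threshold]
  out[mis[unique(hit)]] <- TRUE
  out
}

#' Count neo-epitopes in a mutation set
#'
#' A mutation contributes one neo-epitope when at least one of its mutant
#' 9-mers binds at least one HLA allele (IC50 at or below 500 nM under the
#' predicate) and its gene and transcript RPKM both exceed 1 (highly
#' similar neo-antigens from one mutation count as one).  Mutations without
#' expression values are excluded with a warning.
#'
#' @param mutations data.frame with \code{gene}, \code{aa_pos},
#'   \code{aa_alt}, \code{effect} columns.
#' @param gene_model gene model providing protein sequences.
#' @param alleles character vector of HLA alleles.
#' @param predicate binding predicate (see \code{\link{hash_binder}}).
#' @param expression optional data.frame with \code{gene},
#'   \code{gene_rpkm}, \code{transcript_rpkm}; \code{NULL} skips the
#'   expression filter.
#' @param ic50_threshold binding threshold in nM.
#' @param min_rpkm expression floor (strictly greater than).
#' @param window peptide window width.
#' @return list with \code{count} and logical \code{is_neoepitope} per row.
#' @export
count_neoepitopes <- function(mutations, gene_model, alleles, predicate,
                              expression = NULL, ic50_threshold = 500,
                              min_rpkm = 1, window = 17) {
  binds <- mutations_bind_any(mutations, gene_model, alleles, predicate,
                              ic50_threshold, window)
  expressed <- rep(TRUE, nrow(mutations))
  if (!is.null(expression)) {
    idx <- match(mutations$gene, expression$gene)
    missing <- is.na(idx)
    if (any(missing)) {
      warning(sprintf("%d mutations lack expression values and were excluded",
                      sum(missing)))
      expressed[missing] <- FALSE
    }
    ok <- !missing
    expressed[ok] <- expression$gene_rpkm[idx[ok]] > min_rpkm &
      expression$transcript_rpkm[idx[ok]] > min_rpkm
  }
  neo <- binds & expressed
  list(count = sum(neo), is_neoepitope = neo)
}

ratio_with_conventions <- function(observed, expected) {
  # expected 0 with observed > 0 counts as ratio > 1; both 0 as exactly 1
  ifelse(expected == 0, ifelse(observed > 0, Inf, 1),
         observed / expected)
}

#' Observed-vs-expected neo-epitope test for one sample
#'
#' Simulates \code{n_replicates} context-matched mutation sets, counts
#' neo-epitopes in each with the identical machinery used for the observed
#' set, and reports the per-replicate observed/expected ratios and the
#' empirical p-value (k + 1)/(n + 1) where k is the number of replicates
#' with ratio >= 1.  All replicate ratios below one therefore give
#' p = 1/101, approximately 0.01 at the default 100 replicates; small p
#' indicates neo-epitope depletion (immunoediting).
#'
#' @param mutations observed mutation table (\code{ref}, \code{alt},
#'   \code{context}, \code{gene}, \code{aa_pos}, \code{aa_alt},
#'   \code{effect}).
#' @param rates named gene rates.
#' @param gene_model gene model (sequences, coverage, context index).
#' @param alleles HLA alleles of the patient.
#' @param predicate binding predicate.
#' @param expression optional expression table (see
#'   \code{\link{count_neoepitopes}}).
#' @param sim_expression expression table applied to simulated sets;
#'   defaults to \code{expression} matched by gene.
#' @param n_replicates number of simulated datasets (>= 10; default 100).
#' @param seed integer seed.
#' @return object of class \code{neoepitope_test}: list with
#'   \code{observed}, \code{expected} (vector), \code{ratios},
#'   \code{empirical_p}, \code{n_replicates}.
#' @export
observed_expected_test <- function(mutations, rates, gene_model, alleles,
                                   predicate, expression = NULL,
                                   sim_expression = expression,
                                   n_replicates = 100, seed = 1,
                                   placer = NULL) {
  if (n_replicates < 10) stop("n_replicates must be at least 10")
  obs <- count_neoepitopes(mutations, gene_model, alleles, predicate,
                           expression)$count
  if (is.null(placer)) placer <- context_placer(gene_model, rates)
  ch <- channel_of(mutations$ref, mutations$alt, mutations$context)
  if (any(is.na(ch)))
    stop("observed mutations contain invalid substitutions/contexts")
  parts <- channel_parts(ch)
  n_mut <- nrow(mutations)
  # all replicates placed and scored in one vectorised batch
  rep_idx <- rep(seq_len(n_replicates), each = n_mut)
  big_parts <- parts[rep(seq_len(n_mut), n_replicates), , drop = FALSE]
  big <- with_seed(derive_seed(seed, 1), {
    placed <- placer(big_parts$context)
    annotate_placed(placed, big_parts, gene_model)
  })
  # hard invariant: simulation preserves every trinucleotide context
  stopifnot(identical(pyr_context3(big$context)$context,
                      big_parts$context))
  neo <- count_neoepitopes(big, gene_model, alleles, predicate,
                           sim_expression)$is_neoepitope
  expected <- as.numeric(tapply(neo, rep_idx, sum))
  ratios <- ratio_with_conventions(obs, expected)
  k <- sum(ratios >= 1)
  structure(list(observed = obs, expected = expected, ratios = ratios,
                 empirical_p = (k + 1) / (n_replicates + 1),
                 n_replicates = n_replicates),
            class = "neoepitope_test")
}

#' @export
print.neoepitope_test <- function(x, ...) {
  cat(sprintf(
    "neoepitope_test: observed %d, mean expected %.2f, p = %.4f (%d reps)\n",
    x$observed, mean(x$expected), x$empirical_p, x$n_replicates))
  invisible(x)
}

#' Grouped mean-ratio null for combined metastases
#'
#' For a group of samples (a case, or an organ across cases) the observed
#' statistic is the mean of the per-sample mean observed/expected ratios.
#' The null distribution is built from \code{n_outer} replicates: each
#' replicate simulates a pseudo-observed mutation set per sample, runs
#' \code{n_inner} further simulations against it, and records the group
#' mean ratio.  p = (number of null means <= observed + 1)/(n_outer + 1);
#' small p means the group's neo-epitope yield is lower than simulation
#' predicts.
#'
#' @param sample_list named list; each element a list with
#'   \code{mutations}, \code{alleles} and optional \code{expression}.
#' @param rates,gene_model,predicate shared machinery.
#' @param n_outer,n_inner replicate counts (defaults 20 and 100).
#' @param seed integer seed.
#' @return list with \code{observed_mean_ratio}, \code{null_means},
#'   \code{p}, \code{per_sample} (tests for the observed data).
#' @export
grouped_mean_ratio_null <- function(sample_list, rates, gene_model,
                                    predicate, n_outer = 20, n_inner = 100,
                                    seed = 1) {
  if (length(sample_list) < 2) {
    s <- sample_list[[1]]
    return(observed_expected_test(s$mutations, rates, gene_model,
                                  s$alleles, predicate, s$expression,
                                  n_replicates = n_inner, seed = seed))
  }
  placer <- context_placer(gene_model, rates)
  per_sample <- lapply(seq_along(sample_list), function(i) {
    s <- sample_list[[i]]
    observed_expected_test(s$mutations, rates, gene_model, s$alleles,
                           predicate, s$expression,
                           n_replicates = n_inner,
                           seed = derive_seed(seed, i), placer = placer)
  })
  finite_mean <- function(r) mean(pmin(r, 10))  # cap Inf ratios
  observed_mean <- mean(vapply(per_sample,
                               function(t) finite_mean(t$ratios), 0))
  null_means <- numeric(n_outer)
  for (o in seq_len(n_outer)) {
    ratios_o <- vapply(seq_along(sample_list), function(i) {
      s <- sample_list[[i]]
      pseudo <- simulate_mutation_set(
        s$mutations, rates, gene_model,
        seed = derive_seed(seed, 1000 + o * 100 + i), placer = placer)
      t <- observed_expected_test(pseudo, rates, gene_model, s$alleles,
                                  predicate, s$expression,
                                  n_replicates = n_inner,
                                  seed = derive_seed(seed, 2000 + o * 100 + i),
                                  placer = placer)
      finite_mean(t$ratios)
    }, 0)
    null_means[o] <- mean(ratios_o)
  }
  p <- (sum(null_means <= observed_mean) + 1) / (n_outer + 1)
  list(observed_mean_ratio = observed_mean, null_means = null_means,
       p = p, per_sample = per_sample)
}

#' Assess HLA loss of heterozygosity and its neo-epitope impact
#'
#' An allele is called lost when its locus copy number is below 0.5 with a
#' p-value below 0.05.  A neo-epitope associates with the lost allele(s)
#' when every allele it binds is lost; the fraction of such neo-epitopes is
#' returned.
#'
#' @param allele_table data.frame with \code{allele}, \code{copy_number},
#'   \code{p_value}.
#' @param neo_binding optional named list: neo-epitope id -> character
#'   vector of binding alleles.
#' @param cn_threshold,p_threshold LOH call thresholds.
#' @return list with \code{calls} (data.frame + \code{lost}) and
#'   \code{fraction_lost_restricted} (NA when no neo-epitopes given).
#' @export
hla_loh_assess <- function(allele_table, neo_binding = NULL,
                           cn_threshold = 0.5, p_threshold = 0.05) {
  stopifnot(all(c("allele", "copy_number", "p_value") %in%
                  names(allele_table)))
  calls <- allele_table
  calls$lost <- calls$copy_number < cn_threshold &
    calls$p_value < p_threshold
  frac <- NA_real_
  if (!is.null(neo_binding) && length(neo_binding)) {
    lost_alleles <- calls$allele[calls$lost]
    known <- vapply(neo_binding, function(a) all(a %in% calls$allele),
                    TRUE)
    if (!all(known))
      warning("neo-epitopes binding unlisted alleles were skipped")
    nb <- neo_binding[known]
    if (length(nb))
      frac <- mean(vapply(nb, function(a) all(a %in% lost_alleles), TRUE))
  }
  list(calls = calls, fraction_lost_restricted = frac)
}
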