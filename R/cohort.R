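#' Synthetic signature catalog
#'
#' Generates a catalog of sparse 96-channel mutational signatures with the
#' qualitative structure of curated catalogs (a handful of dominant channels
#' on a low background).  Columns are normalised to sum to 1.  This is a
#' synthetic stand-in: it is not a redistribution of any published catalog.
#'
#' @param n_signatures number of signatures (columns).
#' @param n_peaks number of dominant channels per signature.
#' @param seed integer seed.
#' @return 96 x K numeric matrix; rownames are channel labels, colnames
#'   \code{"SBS_S1"}, ...
#' @export
synthetic_signature_catalog <- function(n_signatures = 4, n_peaks = 6,
                                        seed = 1) {
  check_count(n_signatures, "n_signatures")
  with_seed(seed, {
    S <- matrix(0, 96, n_signatures,
                dimnames = list(CHANNELS,
                                paste0("SBS_S", seq_len(n_signatures))))
    for (k in seq_len(n_signatures)) {
      bg <- runif(96, 0, 0.2)
      peaks <- sample.int(96, n_peaks)
      bg[peaks] <- bg[peaks] + runif(n_peaks, 3, 10)
      S[, k] <- bg / sum(bg)
    }
    S
  })
}

#' Configuration for the synthetic multi-metastasis cohort generator
#'
#' All downstream modules are exercised on cohorts drawn from this
#' configuration.  Defaults describe a cohort of ten cases, each with 5-20
#' metastases partitioned into up to three clades, stem/clade/private
#' mutations drawn from a four-signature mixture, binomial read counts
#' around purity x CCF / 2 at Poisson depth, a stem > clade > private
#' mutant-allele expression gradient, power-law TCR clone sizes with shared
#' expanded clones, and an optional neo-epitope depletion effect
#' (\code{depletion_strength} multiplies the retention probability of
#' binder-generating mutations; 1 means no immunoediting).
#'
#' @param n_cases number of cases (patients).
#' @param metastases_range integer length-2 range of metastases per case.
#' @param n_clades clades per case (capped at the number of metastases).
#' @param stem_mean,clade_mean,private_mean Poisson means for mutation
#'   counts on the root edge, each clade edge, and each leaf edge.
#' @param signature_mixture named non-negative weights over catalog columns,
#'   summing to 1.
#' @param signature_catalog 96 x K signature matrix (rows in channel order).
#' @param purity_range tumor purity range (fractions).
#' @param depth_mean mean sequencing depth (reads).
#' @param subclonal_fraction fraction of stem/clade mutations given CCF < 1.
#' @param expression_gradient named means (stem, clade, private) of
#'   log2 mutant-allele expression.
#' @param tcr_clones_per_site clones per metastasis repertoire.
#' @param clone_size_exponent power-law exponent for clone sizes.
#' @param tcr_shared_stem,tcr_shared_clade fractions of each site's clones
#'   shared case-wide (stem) or clade-wide.
#' @param binder_rate probability that a random (peptide, allele) pair is a
#'   binder under the toy predicate.
#' @param depletion_strength retention multiplier in [0, 1] for
#'   binder-generating mutations (1 = no immunoediting).
#' @param hla_loh_cases number of cases given an HLA LOH event.
#' @param organ_mode \code{"clade"} (metastases in one clade share an organ)
#'   or \code{"random"}.
#' @param n_genes size of the synthetic gene universe.
#' @param cells_per_sample centroids per digitised-slide point set.
#' @param seed master integer seed; every random draw flows from it.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_cases = 10,
                          metastases_range = c(5, 20),
                          n_clades = 3,
                          stem_mean = 200,
                          clade_mean = 120,
                          private_mean = 25,
                          signature_mixture = NULL,
                          signature_catalog = NULL,
                          purity_range = c(0.3, 0.9),
                          depth_mean = 150,
                          subclonal_fraction = 0.25,
                          expression_gradient = c(stem = 2.5, clade = 1.5,
                                                  private = 0.5),
                          tcr_clones_per_site = 150,
                          clone_size_exponent = 2.0,
                          tcr_shared_stem = 0.08,
                          tcr_shared_clade = 0.12,
                          binder_rate = 0.01,
                          depletion_strength = 1,
                          hla_loh_cases = 1,
                          organ_mode = c("clade", "random"),
                          n_genes = 120,
                          cells_per_sample = 400,
                          seed = 1) {
  organ_mode <- match.arg(organ_mode)
  if (is.null(signature_catalog))
    signature_catalog <- synthetic_signature_catalog(seed = 99)
  if (is.null(signature_mixture)) {
    signature_mixture <- setNames(rep(1 / ncol(signature_catalog),
                                      ncol(signature_catalog)),
                                  colnames(signature_catalog))
  }
  check_count(n_cases, "n_cases")
  if (length(metastases_range) != 2 || metastases_range[1] < 2 ||
      metastases_range[2] < metastases_range[1])
    stop_config("metastases_range", "must be an increasing range with min >= 2")
  check_count(n_clades, "n_clades")
  for (f in c("stem_mean", "clade_mean", "private_mean"))
    if (get(f) < 0) stop_config(f, "must be non-negative")
  if (any(signature_mixture < 0) ||
      abs(sum(signature_mixture) - 1) > 1e-9)
    stop_config("signature_mixture",
                "weights must be non-negative and sum to 1")
  if (!all(names(signature_mixture) %in% colnames(signature_catalog)))
    stop_config("signature_mixture", "names must match catalog columns")
  check_fraction(purity_range, "purity_range")
  check_count(depth_mean, "depth_mean")
  check_fraction(subclonal_fraction, "subclonal_fraction")
  if (!all(c("stem", "clade", "private") %in% names(expression_gradient)))
    stop_config("expression_gradient", "needs stem, clade, private entries")
  check_count(tcr_clones_per_site, "tcr_clones_per_site")
  if (clone_size_exponent <= 0)
    stop_config("clone_size_exponent", "must be positive")
  check_fraction(tcr_shared_stem, "tcr_shared_stem")
  check_fraction(tcr_shared_clade, "tcr_shared_clade")
  check_fraction(binder_rate, "binder_rate")
  check_fraction(depletion_strength, "depletion_strength")
  check_count(hla_loh_cases, "hla_loh_cases", min = 0)
  check_count(n_genes, "n_genes", min = 2)
  check_count(cells_per_sample, "cells_per_sample", min = 51)
  check_count(seed, "seed", min = 0)

  structure(list(
    n_cases = n_cases, metastases_range = metastases_range,
    n_clades = n_clades, stem_mean = stem_mean, clade_mean = clade_mean,
    private_mean = private_mean, signature_mixture = signature_mixture,
    signature_catalog = signature_catalog, purity_range = purity_range,
    depth_mean = depth_mean, subclonal_fraction = subclonal_fraction,
    expression_gradient = expression_gradient,
    tcr_clones_per_site = tcr_clones_per_site,
    clone_size_exponent = clone_size_exponent,
    tcr_shared_stem = tcr_shared_stem, tcr_shared_clade = tcr_shared_clade,
    binder_rate = binder_rate, depletion_strength = depletion_strength,
    hla_loh_cases = hla_loh_cases, organ_mode = organ_mode,
    n_genes = n_genes, cells_per_sample = cells_per_sample, seed = seed
  ), class = "cohort_config")
}

# ---------------------------------------------------------------------------
# Gene models: synthetic coding sequences (no internal stops), proteins,
# per-base coverage weights and a pyrimidine-context position index.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

make_gene_models <- function(n_genes, codon_range = c(150, 400)) {
  gene <- sprintf("GENE%04d", seq_len(n_genes))
  n_codon <- sample(codon_range[1]:codon_range[2], n_genes, replace = TRUE)
  seqs <- vapply(n_codon, function(k)
    paste(sample(SENSE_CODONS, k, replace = TRUE), collapse = ""),
    character(1))
  prot <- vapply(seqs, function(s) {
    k <- nchar(s) / 3
    paste(translate_codons(substring(s, 3 * seq_len(k) - 2, 3 * seq_len(k))),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  coverage <- lapply(n_codon * 3, function(L) rbeta(L, 8, 2))
  names(seqs) <- names(prot) <- names(coverage) <- gene

  # context index: every interior position, keyed by pyrimidine context
  idx <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    s <- seqs[i]
    L <- nchar(s)
    tri <- substring(s, 1:(L - 2), 3:L)
    data.frame(gene = gene[i], pos = 2:(L - 1), tri = tri,
               covw = coverage[[i]][2:(L - 1)], stringsAsFactors = FALSE)
  }))
  pc <- pyr_context3(idx$tri)
  idx$ctx <- pc$context
  idx$strand <- pc$strand
  list(gene = gene, seq = seqs, protein = prot, coverage = coverage,
       index = split(idx[c("gene", "pos", "strand", "covw")], idx$ctx))
}

# fast 3-mer pyrimidine collapapse (vectorised, no strsplit)
pyr_context3 <- function(tri) {
  mid <- substr(tri, 2, 2)
  flip <- mid %in% c("A", "G")
  out <- tri
  if (any(flip)) {
    f <- tri[flip]
    out[flip] <- paste0(comp_base(substr(f, 3, 3)),
                        comp_base(substr(f, 2, 2)),
                        comp_base(substr(f, 1, 1)))
  }
  list(context = out, strand = ifelse(flip, "-", "+"))
}

# Placement machine: gene chosen proportional to its relative rate among
# genes carrying the context, position within gene proportional to the
# per-base coverage weight.  Returns one sampler usable for both cohort
# generation and mutation-set simulation.
context_placer <- function(gene_model, rates) {
  tabs <- lapply(gene_model$index, function(df) {
    r <- rates[df$gene]
    r[is.na(r)] <- 0
    cov_sum <- tapply(df$covw, df$gene, sum)[df$gene]
    w <- r * df$covw / cov_sum
    df$w <- as.numeric(w)
    df[df$w > 0, , drop = FALSE]
  })
  function(ctx) {
    out <- data.frame(gene = character(length(ctx)),
                      pos = integer(length(ctx)),
                      strand = character(length(ctx)),
                      stringsAsFactors = FALSE)
    for (c0 in unique(ctx)) {
      tab <- tabs[[c0]]
      if (is.null(tab) || nrow(tab) == 0)
        stop(sprintf("no genomic position carries context %s", c0))
      sel <- which(ctx == c0)
      rows <- sample.int(nrow(tab), length(sel), replace = TRUE,
                         prob = tab$w)
      out$gene[sel] <- tab$gene[rows]
      out$pos[sel] <- tab$pos[rows]
      out$strand[sel] <- tab$strand[rows]
    }
    out
  }
}

# Annotate placed mutations: reference-strand ref/alt/context, protein
# coordinates and amino-acid change.
annotate_placed <- function(placed, parts, gene_model) {
  plus <- placed$strand == "+"
  ref <- ifelse(plus, parts$ref, comp_base(parts$ref))
  alt <- ifelse(plus, parts$alt, comp_base(parts$alt))
  context <- ifelse(plus, parts$context,
                    paste0(comp_base(substr(parts$context, 3, 3)),
                           comp_base(substr(parts$context, 2, 2)),
                           comp_base(substr(parts$context, 1, 1))))
  seqs <- gene_model$seq[placed$gene]
  ci <- (placed$pos - 1L) %/% 3L + 1L
  off <- (placed$pos - 1L) %% 3L + 1L
  codon <- substr(seqs, 3 * ci - 2, 3 * ci)
  mut_codon <- codon
  substr(mut_codon, off, off) <- alt
  aa_ref <- translate_codons(codon)
  aa_alt <- unname(Biostrings::GENETIC_CODE[mut_codon])
  effect <- ifelse(aa_alt == "*", "truncating",
                   ifelse(aa_ref == aa_alt, "silent", "missense"))
  data.frame(gene = placed$gene, pos = placed$pos, ref = ref, alt = alt,
             context = context, aa_pos = ci, aa_ref = aa_ref,
             aa_alt = aa_alt, effect = effect, stringsAsFactors = FALSE)
}

# random recursive bipartition of 1..n into k groups
random_partition <- function(n, k) {
  groups <- list(seq_len(n))
  while (length(groups) < k) {
    splittable <- which(vapply(groups, length, 1L) >= 2)
    if (!length(splittable)) break
    g <- if (length(splittable) == 1) splittable else sample(splittable, 1)
    members <- groups[[g]]
    cut <- sample(seq_len(length(members) - 1), 1)
    perm <- sample(members)
    groups[[g]] <- sort(perm[seq_len(cut)])
    groups[[length(groups) + 1]] <- sort(perm[-seq_len(cut)])
  }
  groups[order(vapply(groups, min, 1L))]
}

power_law_sizes <- function(n, alpha, smax = 500) {
  s <- seq_len(smax)
  sample(s, n, replace = TRUE, prob = s^(-alpha))
}

random_cdr3 <- function(n) {
  k <- sample(10:15, n, replace = TRUE)
  vapply(k, function(m)
    paste(sample(SENSE_CODONS, m, replace = TRUE), collapse = ""),
    character(1))
}

ORGAN_POOL <- c("liver", "lung", "brain", "bone", "lymph_node", "skin",
                "ovary", "pleura")

#' Generate a synthetic multi-metastasis cohort
#'
#' Draws a complete cohort under a \code{\link{cohort_config}}: per-case
#' random clade trees with stem/clade/private mutations sampled from the
#' configured signature mixture and placed at genomic positions that carry
#' the drawn trinucleotide context; binomial alt-read counts at Poisson
#' depth around purity x CCF / 2; lineage-graded mutant-allele expression; a
#' clade-structured immune expression level driving immune-gene TPM,
#' repertoire size and lymphocyte density; TCR repertoires with shared
#' expanded clones; HLA genotypes with optional LOH; and spatially clustered
#' cell centroids.  When \code{depletion_strength < 1}, missense mutations
#' whose mutant 9-mers bind an HLA allele under the toy predicate are
#' retained only with that probability (re-placed at a context-matched
#' position otherwise), creating immunoedited cases.  A ground-truth
#' manifest records lineage labels, per-sample signature exposures, TCR
#' sharing labels and HLA LOH events.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{synthetic_cohort}: list with elements
#'   \code{config}, \code{gene_model}, \code{reference_catalog},
#'   \code{cases} (one list per case) and \code{manifest}.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("config", "must be created by cohort_config()")
  with_seed(config$seed, {
    gene_model <- make_gene_models(config$n_genes)
    ref_counts <- generate_reference_catalog(config$n_genes,
                                             seed = derive_seed(config$seed, 0))
    rates <- setNames(ref_counts$count / sum(ref_counts$count),
                      ref_counts$gene)
    placer <- context_placer(gene_model, rates)
    cases <- vector("list", config$n_cases)
    for (i in seq_len(config$n_cases)) {
      case_seed <- derive_seed(config$seed, i)
      cases[[i]] <- with_seed(case_seed, {
        generate_case(sprintf("CASE%02d", i), config, gene_model, placer,
                      loh = i <= config$hla_loh_cases)
      })
    }
    names(cases) <- vapply(cases, `[[`, "", "case_id")
    manifest <- list(
      seed = config$seed,
      depletion_strength = config$depletion_strength,
      signature_mixture = config$signature_mixture,
      cases = lapply(cases, function(cs) list(
        lineage = setNames(cs$mutations$lineage, cs$mutations$mutation_id),
        true_exposures = cs$true_exposures,
        tcr_sharing = cs$tcr_truth,
        organ = cs$organ,
        hla_lost = cs$hla_lost,
        immune_level = cs$immune_level
      ))
    )
    structure(list(config = config, gene_model = gene_model,
                   reference_catalog = ref_counts, cases = cases,
                   manifest = manifest),
              class = "synthetic_cohort")
  })
}

generate_case <- function(case_id, config, gene_model, placer, loh = FALSE) {
  n_s <- if (config$metastases_range[1] == config$metastases_range[2])
    config$metastases_range[1] else
      sample(config$metastases_range[1]:config$metastases_range[2], 1)
  sample_id <- sprintf("%s_M%02d", case_id, seq_len(n_s))
  purity <- runif(n_s, config$purity_range[1], config$purity_range[2])
  k <- min(config$n_clades, n_s)
  clades <- random_partition(n_s, k)
  clade_of <- integer(n_s)
  for (j in seq_along(clades)) clade_of[clades[[j]]] <- j

  organ <- if (config$organ_mode == "clade") {
    pool <- sample(ORGAN_POOL, length(clades))
    pool[clade_of]
  } else sample(ORGAN_POOL, n_s, replace = TRUE)
  names(organ) <- sample_id

  # --- mutation counts per edge ------------------------------------------
  n_stem <- max(1L, rpois(1, config$stem_mean))
  clade_sizes <- vapply(clades, length, 1L)
  n_clade <- ifelse(clade_sizes >= 2, rpois(length(clades),
                                            config$clade_mean), 0L)
  n_priv <- rpois(n_s, config$private_mean)

  lineage <- c(rep("stem", n_stem),
               rep("clade", sum(n_clade)),
               rep("private", sum(n_priv)))
  clade_idx <- c(rep(NA_integer_, n_stem),
                 rep(seq_along(clades), n_clade),
                 rep(NA_integer_, sum(n_priv)))
  priv_sample <- c(rep(NA_integer_, n_stem + sum(n_clade)),
                   rep(seq_len(n_s), n_priv))
  n_mut <- length(lineage)

  # --- channels from the signature mixture -------------------------------
  w <- config$signature_mixture
  S <- config$signature_catalog[, names(w), drop = FALSE]
  sig_idx <- sample(seq_along(w), n_mut, replace = TRUE, prob = w)
  channel <- character(n_mut)
  for (kk in seq_along(w)) {
    sel <- sig_idx == kk
    if (any(sel))
      channel[sel] <- sample(CHANNELS, sum(sel), replace = TRUE,
                             prob = S[, kk])
  }
  parts <- channel_parts(channel)
  placed <- placer(parts$context)
  ann <- annotate_placed(placed, parts, gene_model)

  # --- HLA genotype & LOH -------------------------------------------------
  hla <- paste0("HLA-", rep(c("A", "B", "C"), each = 2), "*S",
                sprintf("%02d", sample(1:40, 6, replace = TRUE)))
  hla <- make.unique(hla, sep = "x")
  hla_lost <- NULL
  cn <- rnorm(6, 1, 0.08)
  pv <- runif(6, 0.1, 0.9)
  if (loh) {
    lost_i <- sample(6, 1)
    cn[lost_i] <- runif(1, 0.1, 0.4)
    pv[lost_i] <- runif(1, 0.001, 0.04)
    hla_lost <- hla[lost_i]
  }
  hla_table <- data.frame(allele = hla, copy_number = cn, p_value = pv,
                          stringsAsFactors = FALSE)

  # --- immunoediting: thin binder-generating mutations --------------------
  predicate <- hash_binder(rate = config$binder_rate)
  if (config$depletion_strength < 1) {
    is_binder <- mutations_bind_any(ann, gene_model, hla, predicate)
    drop <- is_binder & runif(n_mut) > config$depletion_strength
    for (m in which(drop)) {
      for (attempt in 1:25) {
        p1 <- placer(parts$context[m])
        a1 <- annotate_placed(p1, parts[m, , drop = FALSE], gene_model)
        if (a1$effect != "missense" ||
            !mutations_bind_any(a1, gene_model, hla, predicate)) {
          ann[m, ] <- a1
          break
        }
      }
    }
  }

  mutation_id <- sprintf("%s_MUT%05d", case_id, seq_len(n_mut))
  mutations <- cbind(data.frame(case_id = case_id,
                                mutation_id = mutation_id,
                                chrom = ann$gene, stringsAsFactors = FALSE),
                     ann[, c("gene", "pos", "ref", "alt", "context",
                             "aa_pos", "aa_ref", "aa_alt", "effect")])
  mutations$channel <- channel
  mutations$signature <- names(w)[sig_idx]
  mutations$lineage <- lineage

  # --- presence, CCF, reads ----------------------------------------------
  presence <- matrix(FALSE, n_mut, n_s,
                     dimnames = list(mutation_id, sample_id))
  presence[lineage == "stem", ] <- TRUE
  for (j in seq_along(clades))
    presence[which(clade_idx == j), clades[[j]]] <- TRUE
  priv_rows <- which(lineage == "private")
  presence[cbind(priv_rows, priv_sample[priv_rows])] <- TRUE

  ccf <- rep(1, n_mut)
  sc <- lineage %in% c("stem", "clade") &
    runif(n_mut) < config$subclonal_fraction
  ccf[sc] <- runif(sum(sc), 0.2, 0.7)

  depth <- matrix(rpois(n_mut * n_s, config$depth_mean), n_mut, n_s,
                  dimnames = dimnames(presence))
  pmat <- outer(ccf, purity) / 2
  alt_reads <- matrix(0L, n_mut, n_s, dimnames = dimnames(presence))
  pres_idx <- which(presence)
  alt_reads[pres_idx] <- rbinom(length(pres_idx), depth[pres_idx],
                                pmat[pres_idx])
  vaf <- ifelse(depth > 0, alt_reads / depth, 0)

  # --- expression ---------------------------------------------------------
  grad <- config$expression_gradient[lineage]
  x <- rnorm(n_mut, grad, 0.8)
  x[x < 0] <- 0
  rna_vaf <- runif(n_mut, 0.2, 0.6)
  mut_tpm <- (2^x - 1) / rna_vaf
  mut_expression <- data.frame(mutation_id = mutation_id,
                               gene = mutations$gene,
                               gene_tpm = mut_tpm, rna_vaf = rna_vaf,
                               stringsAsFactors = FALSE)

  clade_effect <- rlnorm(length(clades), 0, 0.6)
  immune_level <- clade_effect[clade_of] * rlnorm(n_s, 0, 0.4)
  names(immune_level) <- sample_id
  ig <- immune_genes()
  expr_genes <- c(gene_model$gene, ig)
  tpm <- matrix(rlnorm(length(expr_genes) * n_s, meanlog = 2, sdlog = 1),
                length(expr_genes), n_s,
                dimnames = list(expr_genes, sample_id))
  tpm[ig, ] <- sweep(tpm[ig, , drop = FALSE], 2, immune_level, `*`)

  # --- genomic sample tree ------------------------------------------------
  tree <- case_tree(sample_id, clades, n_clade, n_priv)

  # --- TCR repertoires ----------------------------------------------------
  rep_out <- generate_repertoires(case_id, sample_id, clades, clade_of,
                                  config, immune_level)

  # --- point sets ---------------------------------------------------------
  lymph <- pmin(0.35, 0.08 * immune_level / mean(immune_level) + 0.04)
  pointsets <- lapply(seq_len(n_s), function(s)
    generate_pointset(config$cells_per_sample,
                      cluster_layout = list(type = "clustered",
                                            class_probs = c(cancer = 1 - lymph[s] - 0.25,
                                                            stromal = 0.25,
                                                            lymphocyte = lymph[s])),
                      seed = floor(runif(1) * 2^30)))
  names(pointsets) <- sample_id

  # --- ground-truth exposures --------------------------------------------
  true_exposures <- sapply(sample_id, function(s) {
    tab <- table(factor(mutations$signature[presence[, s]],
                        levels = names(w)))
    as.numeric(tab)
  })
  rownames(true_exposures) <- names(w)

  list(case_id = case_id, sample_id = sample_id, purity = purity,
       organ = organ, clades = clades, clade_of = clade_of,
       mutations = mutations, presence = presence, depth = depth,
       alt_reads = alt_reads, vaf = vaf, ccf = ccf,
       mut_expression = mut_expression, tpm = tpm,
       immune_level = immune_level, tree = tree,
       repertoires = rep_out$repertoires, tcr_truth = rep_out$truth,
       hla = hla, hla_table = hla_table, hla_lost = hla_lost,
       pointsets = pointsets, true_exposures = true_exposures)
}

# Edge-weighted case tree: root -> clade nodes -> leaves; edge weights are
# the mutation counts generated on each edge (clade edges for multi-sample
# clades, private counts on leaf edges).
case_tree <- function(sample_id, clades, n_clade, n_priv) {
  leaf_nwk <- function(j) {
    members <- clades[[j]]
    parts <- sprintf("%s:%d", sample_id[members], n_priv[members])
    if (length(members) == 1) parts else
      sprintf("(%s):%d", paste(parts, collapse = ","), n_clade[j])
  }
  nwk <- sprintf("(%s):0;", paste(vapply(seq_along(clades), leaf_nwk, ""),
                                  collapse = ","))
  tr <- ape::read.tree(text = nwk)
  tr
}

generate_repertoires <- function(case_id, sample_id, clades, clade_of,
                                 config, immune_level) {
  n_s <- length(sample_id)
  npc <- config$tcr_clones_per_site
  n_stem_cl <- max(1L, round(config$tcr_shared_stem * npc))
  n_clade_cl <- ifelse(vapply(clades, length, 1L) >= 2,
                       max(1L, round(config$tcr_shared_clade * npc)), 0L)

  new_clones <- function(n, label) {
    cdr3_nt <- random_cdr3(n)
    chain <- ifelse(runif(n) < 0.55, "beta", "alpha")
    v_call <- ifelse(chain == "beta",
                     sprintf("TRBV%d", sample(1:30, n, replace = TRUE)),
                     sprintf("TRAV%d", sample(1:41, n, replace = TRUE)))
    j_call <- ifelse(chain == "beta",
                     sprintf("TRBJ%d-%d", sample(1:2, n, replace = TRUE),
                             sample(1:7, n, replace = TRUE)),
                     sprintf("TRAJ%d", sample(1:61, n, replace = TRUE)))
    aa <- vapply(cdr3_nt, function(s) {
      k <- nchar(s) / 3
      paste(translate_codons(substring(s, 3 * seq_len(k) - 2,
                                       3 * seq_len(k))), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    data.frame(chain = chain, v_call = v_call, j_call = j_call,
               cdr3_nt = cdr3_nt, cdr3_aa = aa, truth = label,
               stringsAsFactors = FALSE)
  }

  stem_pool <- new_clones(n_stem_cl, "stem")
  clade_pools <- lapply(seq_along(clades), function(j)
    if (n_clade_cl[j] > 0) new_clones(n_clade_cl[j], "clade") else NULL)

  repertoires <- vector("list", n_s)
  truth <- list()
  for (s in seq_len(n_s)) {
    cl <- clade_of[s]
    shared <- rbind(stem_pool, clade_pools[[cl]])
    # clone richness varies across sites (Poisson around the configured
    # mean after removing the shared pool)
    n_priv <- rpois(1, max(1, npc - nrow(shared)))
    priv <- new_clones(n_priv, "private")
    all_cl <- rbind(shared, priv)
    sizes <- power_law_sizes(nrow(all_cl), config$clone_size_exponent)
    sizes[all_cl$truth == "stem"] <- sizes[all_cl$truth == "stem"] * 3L
    scale <- max(0.5, immune_level[s])
    counts <- pmax(1L, as.integer(round(sizes * scale * 8)))
    rep_df <- data.frame(sample_id = sample_id[s], all_cl[1:5],
                         duplicate_count = counts,
                         stringsAsFactors = FALSE)
    repertoires[[s]] <- rep_df
    key <- paste(all_cl$cdr3_nt, all_cl$v_call, all_cl$j_call, sep = "|")
    truth[[sample_id[s]]] <- setNames(all_cl$truth, key)
  }
  names(repertoires) <- sample_id
  list(repertoires = repertoires, truth = truth)
}

#' Synthetic gene-level reference mutation catalog
#'
#' Stand-in for a large external cohort's per-gene mutation counts used to
#' derive relative background mutation rates.  Counts are positive and
#' heavy-tailed over the same gene universe the cohort generator uses.
#'
#' @param n_genes number of genes (>= 2).
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{count}.
#' @export
generate_reference_catalog <- function(n_genes, seed = 1) {
  if (!is.numeric(n_genes) || n_genes < 2)
    stop("n_genes must be >= 2")
  with_seed(seed, {
    data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
               count = rnbinom(n_genes, mu = 50, size = 1.2) + 1L,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic cell-centroid point set
#'
#' Generates (x, y) centroids with class labels in
#' \{cancer, stromal, lymphocyte\}, either uniformly over the window or
#' spatially clustered (a fraction of points in Gaussian clusters).
#'
#' @param n_cells number of points (> 50; the density estimator needs at
#'   least N + 1 points).
#' @param cluster_layout list with elements \code{type}
#'   (\code{"uniform"}/\code{"clustered"}), \code{width}, \code{height}
#'   (pixels), \code{n_clusters}, \code{cluster_sd}, \code{cluster_frac} and
#'   \code{class_probs} (named cancer/stromal/lymphocyte).
#' @param seed integer seed.
#' @return data.frame with columns \code{x}, \code{y}, \code{class}.
#' @export
generate_pointset <- function(n_cells,
                              cluster_layout = list(type = "uniform"),
                              seed = 1) {
  if (!is.numeric(n_cells) || n_cells <= 50)
    stop("n_cells must be > 50 (density needs at least N + 1 points)")
  lay <- utils::modifyList(
    list(type = "uniform", width = 2000, height = 2000, n_clusters = 5,
         cluster_sd = 60, cluster_frac = 0.7,
         class_probs = c(cancer = 0.6, stromal = 0.25, lymphocyte = 0.15)),
    cluster_layout)
  with_seed(seed, {
    n_cells <- as.integer(n_cells)
    if (lay$type == "uniform") {
      x <- runif(n_cells, 0, lay$width)
      y <- runif(n_cells, 0, lay$height)
    } else {
      n_cl <- max(0L, as.integer(round(n_cells * lay$cluster_frac)))
      cx <- runif(lay$n_clusters, 0.15 * lay$width, 0.85 * lay$width)
      cy <- runif(lay$n_clusters, 0.15 * lay$height, 0.85 * lay$height)
      which_cl <- sample(lay$n_clusters, n_cl, replace = TRUE)
      x <- c(rnorm(n_cl, cx[which_cl], lay$cluster_sd),
             runif(n_cells - n_cl, 0, lay$width))
      y <- c(rnorm(n_cl, cy[which_cl], lay$cluster_sd),
             runif(n_cells - n_cl, 0, lay$height))
      x <- pmin(pmax(x, 0), lay$width)
      y <- pmin(pmax(y, 0), lay$height)
    }
    p <- lay$class_probs / sum(lay$class_probs)
    cls <- sample(names(p), n_cells, replace = TRUE, prob = p)
    data.frame(x = x, y = y, class = cls, stringsAsFactors = FALSE)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases, seed %d\n",
              length(x$cases), x$config$seed))
  for (cs in x$cases)
    cat(sprintf("  %s: %d metastases, %d mutations, organs: %s\n",
                cs$case_id, length(cs$sample_id), nrow(cs$mutations),
                paste(unique(cs$organ), collapse = "/")))
  invisible(x)
}
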