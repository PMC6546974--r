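#' UMI consensus collapsing with template check
#'
#' Reads are grouped by molecular barcode (UMI).  Barcodes must match the
#' \code{TNNNNTNNNNTNNNNT} template (conserved T at positions 1, 6, 11 and
#' 16); violating groups are discarded.  A group emits a positionwise
#' majority-vote consensus only when the mean pairwise sequence identity
#' within the group exceeds 0.80, otherwise it is discarded.
#'
#' @param reads data.frame with columns \code{umi}, \code{sequence}.
#' @param min_identity identity threshold (strictly greater than).
#' @return data.frame with columns \code{umi}, \code{consensus},
#'   \code{n_reads}.
#' @export
umi_consensus <- function(reads, min_identity = 0.80) {
  if (nrow(reads) == 0)
    return(data.frame(umi = character(0), consensus = character(0),
                      n_reads = integer(0), stringsAsFactors = FALSE))
  t_pos <- c(1, 6, 11, 16)
  ok_umi <- nchar(reads$umi) == 16 &
    vapply(reads$umi, function(u)
      all(substring(u, t_pos, t_pos) == "T"), TRUE, USE.NAMES = FALSE)
  reads <- reads[ok_umi, , drop = FALSE]
  out <- list()
  for (u in unique(reads$umi)) {
    seqs <- reads$sequence[reads$umi == u]
    if (length(seqs) > 1) {
      mats <- strsplit(seqs, "", fixed = TRUE)
      pid <- function(a, b) {
        L <- max(length(a), length(b))
        len <- min(length(a), length(b))
        sum(a[seq_len(len)] == b[seq_len(len)]) / L
      }
      pairs <- utils::combn(length(seqs), 2)
      ident <- mean(apply(pairs, 2, function(p) pid(mats[[p[1]]],
                                                    mats[[p[2]]])))
      if (ident <= min_identity) next
      L <- max(nchar(seqs))
      cons <- vapply(seq_len(L), function(i) {
        col <- vapply(mats, function(m)
          if (i <= length(m)) m[i] else NA_character_, "")
        tab <- table(col[!is.na(col)])
        names(tab)[which.max(tab)]
      }, "")
      cons <- paste(cons, collapse = "")
    } else cons <- seqs
    out[[u]] <- data.frame(umi = u, consensus = cons,
                           n_reads = length(seqs),
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(umi = character(0), consensus = character(0),
                      n_reads = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, c(out, make.row.names = FALSE))
}

clone_key <- function(df, clone_key_cols = c("cdr3_nt", "v_call", "j_call")) {
  do.call(paste, c(df[clone_key_cols], sep = "|"))
}

#' Group clonotypes into clones
#'
#' A clone is the set of reads sharing an identical CDR3 nucleotide
#' sequence and V gene (and J gene under the default \code{"vj"} key);
#' clone size is the summed read/UMI count.
#'
#' @param repertoire data.frame with \code{cdr3_nt}, \code{v_call},
#'   \code{j_call}, \code{duplicate_count} and optionally \code{chain},
#'   \code{cdr3_aa}.
#' @param key \code{"vj"} (CDR3nt + V + J) or \code{"v"} (CDR3nt + V).
#' @return data.frame, one row per clone, with \code{clone_id} and
#'   \code{size}; total size equals the repertoire's total reads.
#' @export
define_clones <- function(repertoire, key = c("vj", "v")) {
  key <- match.arg(key)
  cols <- if (key == "vj") c("cdr3_nt", "v_call", "j_call")
          else c("cdr3_nt", "v_call")
  k <- do.call(paste, c(repertoire[cols], sep = "|"))
  size <- tapply(repertoire$duplicate_count, k, sum)
  first <- !duplicated(k)
  meta_cols <- intersect(c("chain", "v_call", "j_call", "cdr3_nt",
                           "cdr3_aa"), names(repertoire))
  out <- repertoire[first, meta_cols, drop = FALSE]
  out$clone_id <- k[first]
  out$size <- as.integer(size[out$clone_id])
  rownames(out) <- NULL
  out[order(-out$size, out$clone_id), , drop = FALSE]
}

#' Remove public TCR clones
#'
#' Clones found in an external database, or shared between two or more
#' patients of the cohort, are removed from every repertoire.
#'
#' @param patient_repertoires named list (patient -> data.frame of
#'   clonotypes with \code{cdr3_nt}, \code{v_call}, \code{j_call}).
#' @param external_db optional data.frame of clonotypes with the same key
#'   columns (nucleotide CDR3 matching).
#' @param key clone key passed to \code{\link{define_clones}}.
#' @return the list with public clones filtered out of each element.
#' @export
remove_public <- function(patient_repertoires, external_db = NULL,
                          key = c("vj", "v")) {
  key <- match.arg(key)
  cols <- if (key == "vj") c("cdr3_nt", "v_call", "j_call")
          else c("cdr3_nt", "v_call")
  per_patient <- lapply(patient_repertoires, function(df)
    unique(do.call(paste, c(df[cols], sep = "|"))))
  shared <- names(which(table(unlist(lapply(per_patient, unique))) >= 2))
  db_keys <- if (!is.null(external_db))
    unique(do.call(paste, c(external_db[cols], sep = "|"))) else character(0)
  public <- union(shared, db_keys)
  lapply(patient_repertoires, function(df) {
    k <- do.call(paste, c(df[cols], sep = "|"))
    df[!(k %in% public), , drop = FALSE]
  })
}

#' Classify TCR clone sharing across metastases
#'
#' A clone is \emph{stem} when found in all of a case's metastatic sites,
#' \emph{clade} when found in some but not all, and \emph{private} when
#' found in a single site.  Per-site read fractions in each class are the
#' repertoire-composition summary.
#'
#' @param site_repertoires named list (site -> clonotype data.frame with
#'   \code{duplicate_count}).
#' @param key clone key.
#' @return list with \code{labels} (clone key -> class) and
#'   \code{site_fractions} (sites x classes matrix, rows summing to 1).
#' @export
classify_tcr_sharing <- function(site_repertoires, key = c("vj", "v")) {
  key <- match.arg(key)
  if (length(site_repertoires) < 2)
    stop("TCR sharing undefined for a single site")
  cols <- if (key == "vj") c("cdr3_nt", "v_call", "j_call")
          else c("cdr3_nt", "v_call")
  keys <- lapply(site_repertoires, function(df)
    do.call(paste, c(df[cols], sep = "|")))
  n_sites_with <- table(unlist(lapply(keys, unique)))
  n <- length(site_repertoires)
  labels <- ifelse(n_sites_with == n, "stem",
                   ifelse(n_sites_with == 1, "private", "clade"))
  labels <- setNames(as.character(labels), names(n_sites_with))
  site_fractions <- t(vapply(names(site_repertoires), function(s) {
    df <- site_repertoires[[s]]
    cl <- labels[keys[[s]]]
    tot <- sum(df$duplicate_count)
    vapply(c("stem", "clade", "private"), function(lv)
      sum(df$duplicate_count[cl == lv]) / tot, 0)
  }, numeric(3)))
  list(labels = labels, site_fractions = site_fractions)
}

#' Gini index by mean absolute difference
#'
#' G = sum_i sum_j |x_i - x_j| / (2 n^2 xbar), without small-sample
#' correction; 0 for perfectly even distributions.
#'
#' @param x non-negative sizes.
#' @return Gini index in [0, 1).
#' @export
gini_index <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("sizes must be non-negative")
  n <- length(x)
  if (n == 0 || mean(x) == 0) return(0)
  xs <- sort(x)
  # equivalent to the double-sum mean-absolute-difference formula
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(x))
}

# subsample `depth` reads without replacement from a repertoire expanded to
# read level; returns the subsampled clonotype table
subsample_reads <- function(repertoire, depth) {
  reads <- rep(seq_len(nrow(repertoire)), repertoire$duplicate_count)
  pick <- sample(reads, depth)
  tab <- table(pick)
  out <- repertoire[as.integer(names(tab)), , drop = FALSE]
  out$duplicate_count <- as.integer(tab)
  rownames(out) <- NULL
  out
}

#' Subsampled repertoire clonality metrics
#'
#' Each metric is the mean over \code{repeats} subsamples of \code{depth}
#' reads drawn without replacement.  \code{gini_vertex} is the Gini index
#' of reads per unique sequence (vertex), \code{gini_cluster} of unique
#' sequences per clone.  Mean and largest cluster sizes are reported in two
#' dialects: \code{*_pct_reads} (percent of subsample reads in the mean /
#' largest clone, the default interpretation) and \code{*_per_cluster}
#' (reads divided by the number of clusters x 100, the printed-formula
#' form).
#'
#' @param repertoire clonotype data.frame.
#' @param depth subsample depth in reads (default 1000).
#' @param repeats subsample repeats (default 20).
#' @param seed integer seed.
#' @param key clone key.
#' @return named list of means over repeats; \code{NULL} with a warning
#'   when the repertoire holds fewer than \code{depth} reads.
#' @export
subsampled_clonality <- function(repertoire, depth = 1000, repeats = 20,
                                 seed = 1, key = c("vj", "v")) {
  key <- match.arg(key)
  if (depth < 10) stop("depth must be at least 10")
  total <- sum(repertoire$duplicate_count)
  if (total < depth) {
    warning(sprintf("repertoire has %d < %d reads; excluded", total, depth))
    return(NULL)
  }
  with_seed(seed, {
    acc <- matrix(0, repeats, 6,
                  dimnames = list(NULL, c("gini_vertex", "gini_cluster",
                                          "mcs_pct_reads", "lcs_pct_reads",
                                          "mcs_per_cluster",
                                          "lcs_per_cluster")))
    for (r in seq_len(repeats)) {
      sub <- subsample_reads(repertoire, depth)
      vertex_sizes <- tapply(sub$duplicate_count,
                             clone_key(sub), sum)
      clones <- define_clones(sub, key = key)
      # unique sequences (vertices) per clone
      vkey <- clone_key(sub)
      ckey <- if (key == "vj") clone_key(sub) else
        do.call(paste, c(sub[c("cdr3_nt", "v_call")], sep = "|"))
      per_clone_vertices <- tapply(vkey, ckey,
                                   function(v) length(unique(v)))
      clone_reads <- clones$size
      n_clusters <- nrow(clones)
      acc[r, ] <- c(gini_index(vertex_sizes),
                    gini_index(per_clone_vertices),
                    mean(clone_reads) / depth * 100,
                    max(clone_reads) / depth * 100,
                    sum(clone_reads) / n_clusters * 100,
                    max(clone_reads) / n_clusters * 100)
    }
    as.list(colMeans(acc))
  })
}

#' Subsampled clonal overlap coefficient
#'
#' O(i, j) = C_ij / (0.5 (C_i + C_j)) where C_x is the number of clones in
#' sample x and C_ij the number shared, computed per subsample of
#' \code{depth} reads and averaged over \code{repeats}.  Symmetric, in
#' [0, 1].
#'
#' @param rep_i,rep_j clonotype data.frames.
#' @param depth,repeats,seed subsampling controls; \code{depth = NULL}
#'   disables subsampling.
#' @param key clone key.
#' @return mean overlap coefficient, or \code{NA} when either sample fails
#'   the depth requirement.
#' @export
overlap_coefficient <- function(rep_i, rep_j, depth = 1000, repeats = 20,
                                seed = 1, key = c("vj", "v")) {
  key <- match.arg(key)
  o_of <- function(a, b) {
    ci <- unique(clone_key_for(a, key))
    cj <- unique(clone_key_for(b, key))
    length(intersect(ci, cj)) / (0.5 * (length(ci) + length(cj)))
  }
  if (is.null(depth)) return(o_of(rep_i, rep_j))
  if (sum(rep_i$duplicate_count) < depth ||
      sum(rep_j$duplicate_count) < depth) return(NA_real_)
  with_seed(seed, {
    mean(vapply(seq_len(repeats), function(r)
      o_of(subsample_reads(rep_i, depth), subsample_reads(rep_j, depth)),
      0))
  })
}

clone_key_for <- function(df, key) {
  cols <- if (key == "vj") c("cdr3_nt", "v_call", "j_call")
          else c("cdr3_nt", "v_call")
  do.call(paste, c(df[cols], sep = "|"))
}

#' CDR3 amino-acid Jaccard similarity and clustering tree
#'
#' The Jaccard index |A n B| / |A u B| over unique CDR3 amino-acid sets is
#' computed per sample pair (via \code{vegan::vegdist} on the binary
#' presence matrix); samples are clustered on distance 1 - J with
#' complete-linkage agglomeration.
#'
#' @param repertoires named list of clonotype data.frames (needs
#'   \code{cdr3_aa}; filter by \code{chain} beforehand if desired).
#' @param chain optional chain filter ("alpha"/"beta").
#' @return list with \code{similarity} (matrix), \code{hclust} (NULL for
#'   < 3 samples) and \code{tree} (\code{ape::phylo} or NULL).
#' @export
jaccard_tree <- function(repertoires, chain = NULL) {
  sets <- lapply(repertoires, function(df) {
    if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
    unique(df$cdr3_aa)
  })
  all_aa <- unique(unlist(sets))
  pa <- t(vapply(sets, function(s) as.integer(all_aa %in% s),
                 integer(length(all_aa))))
  d <- vegan::vegdist(pa, method = "jaccard", binary = TRUE)
  sim <- 1 - as.matrix(d)
  dimnames(sim) <- list(names(repertoires), names(repertoires))
  if (length(repertoires) < 3)
    return(list(similarity = sim, hclust = NULL, tree = NULL))
  hc <- hclust(d, method = "complete")
  hc$labels <- names(repertoires)
  list(similarity = sim, hclust = hc, tree = ape::as.phylo(hc))
}

# Robinson-Foulds bipartition distance on unrooted topologies; polytomies
# are legitimate here, so the non-binary chatter is muted.
rf_dist <- function(a, b) {
  suppressWarnings(suppressMessages(
    as.numeric(phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))))
}

# organ separation statistic on a symmetric distance matrix: mean
# between-organ distance minus mean within-organ distance (larger = more
# organ-structured); NA when an organ labelling yields no within pairs
organ_separation <- function(d, organ) {
  if (inherits(d, "phylo")) d <- ape::cophenetic.phylo(d)
  labs <- rownames(d)
  same <- outer(organ[labs], organ[labs], `==`)
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  if (!length(within) || !length(between)) return(NA_real_)
  mean(between) - mean(within)
}

#' Permutation tests for organ structure in TCR similarity
#'
#' Two complementary nulls are evaluated.  (1) \emph{Organ concordance}:
#' the organ-separation statistic (mean between-organ minus mean
#' within-organ CDR3 Jaccard distance) is compared against
#' \code{n_perm} random permutations of the organ labels across
#' metastases; \code{p_organ} = (#null >= observed + 1)/(n_perm + 1).
#' (2) \emph{Repertoire structure}: TCR sequences are pooled and
#' reassigned uniformly to metastases preserving per-sample read totals,
#' the Jaccard clustering tree is rebuilt per randomization, and the
#' observed tree is compared with the randomized ones -- and the
#' randomized trees with each other -- by cophenetic correlation;
#' \code{p_structure} is the fraction of randomized trees that are at
#' least as atypical among their peers as the observed tree is.  The
#' Robinson-Foulds distance between each tree and an organ-grouping
#' reference tree gives \code{p_rf} (reshuffle null; smaller RF = more
#' organ-concordant).
#'
#' @param repertoires named list of clonotype data.frames.
#' @param organ named character vector of organ labels per sample (>= 2
#'   organs).
#' @param n_perm randomizations for each null (default 100).
#' @param seed integer seed.
#' @param chain optional chain filter.
#' @return list with \code{observed} (separation), \code{null}
#'   (label-permutation separations), \code{p_organ}, \code{p_structure},
#'   \code{observed_rf}, \code{null_rf}, \code{p_rf}, \code{n_perm}.
#' @export
permutation_organ_test <- function(repertoires, organ, n_perm = 100,
                                   seed = 1, chain = NULL) {
  if (length(repertoires) < 4) stop("need at least 4 samples")
  if (length(unique(organ[names(repertoires)])) < 2)
    stop("need at least 2 organs")
  jt <- jaccard_tree(repertoires, chain)
  d_obs <- 1 - jt$similarity
  obs_tree <- jt$tree
  obs_sep <- organ_separation(d_obs, organ)
  organ_ref <- organ_reference_tree(organ[names(repertoires)])
  obs_rf <- rf_dist(obs_tree, organ_ref)

  pooled <- do.call(rbind, repertoires)
  reads <- rep(seq_len(nrow(pooled)), pooled$duplicate_count)
  totals <- vapply(repertoires, function(df) sum(df$duplicate_count), 0)
  null_sep <- numeric(n_perm)
  null_rf <- numeric(n_perm)
  dvecs <- matrix(0, sum(upper.tri(d_obs)), n_perm + 1)
  ut <- upper.tri(d_obs)
  ord <- rownames(d_obs)
  dvecs[, 1] <- d_obs[ut]
  with_seed(seed, {
    # null 1: organ labels permuted on the observed distance matrix
    for (p in seq_len(n_perm)) {
      po <- setNames(sample(organ[ord]), ord)
      null_sep[p] <- organ_separation(d_obs, po)
    }
    # null 2: reads reshuffled across metastases, trees rebuilt
    for (p in seq_len(n_perm)) {
      shuffled <- sample(reads)
      assign_to <- rep(names(repertoires), totals)
      new_reps <- lapply(split(shuffled, assign_to), function(rows) {
        tab <- table(rows)
        out <- pooled[as.integer(names(tab)), , drop = FALSE]
        out$duplicate_count <- as.integer(tab)
        out
      })
      njt <- jaccard_tree(new_reps[names(repertoires)], chain)
      dvecs[, p + 1] <- (1 - njt$similarity)[ord, ord][ut]
      null_rf[p] <- rf_dist(njt$tree, organ_ref)
    }
  })
  # cophenetic-style correlation of each tree with every other; the
  # observed tree is "structured" when it correlates with the reshuffled
  # trees less than they correlate among themselves
  C <- suppressWarnings(cor(dvecs))
  C[is.na(C)] <- 1  # degenerate constant distance vectors
  mean_to_null <- function(i) mean(C[i, -c(1, i)])
  obs_aff <- mean_to_null(1)
  null_aff <- vapply(2:(n_perm + 1), mean_to_null, 0)
  p_structure <- (sum(null_aff <= obs_aff) + 1) / (n_perm + 1)
  list(observed = obs_sep, null = null_sep,
       p_organ = (sum(null_sep >= obs_sep) + 1) / (n_perm + 1),
       p_structure = p_structure,
       observed_rf = obs_rf, null_rf = null_rf,
       p_rf = (sum(null_rf <= obs_rf) + 1) / (n_perm + 1),
       n_perm = n_perm)
}

# resolved reference tree grouping samples by organ (arbitrary but fixed
# internal resolution; RF only uses the organ bipartitions it induces)
organ_reference_tree <- function(organ) {
  groups <- split(names(organ), organ)
  nwk <- paste0("(", paste(vapply(groups, function(g) {
    if (length(g) == 1) g else paste0("(", paste(g, collapse = ","), ")")
  }, ""), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Concordance of two edge-weighted sample trees
#'
#' Restricted to shared leaves: the cophenetic correlation is the Pearson
#' correlation of the leaf-pair distance vectors, where distance is the
#' sum of edge weights along the path between two leaves; the
#' Robinson-Foulds distance is the bipartition symmetric difference of the
#' two topologies.  The p-value permutes the leaf labels of tree b.
#'
#' @param tree_a,tree_b \code{ape::phylo} trees with overlapping leaf sets
#'   (>= 4 shared leaves).
#' @param n_perm label permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{cophenetic_r}, \code{rf_distance}, \code{p},
#'   \code{shared_leaves}.
#' @export
tree_concordance <- function(tree_a, tree_b, n_perm = 1000, seed = 1) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 4) stop("need at least 4 shared leaves")
  ta <- ape::keep.tip(tree_a, shared)
  tb <- ape::keep.tip(tree_b, shared)
  da <- ape::cophenetic.phylo(ta)[shared, shared]
  db <- ape::cophenetic.phylo(tb)[shared, shared]
  ut <- upper.tri(da)
  r_obs <- cor(da[ut], db[ut])
  rf <- rf_dist(ta, tb)
  null_r <- numeric(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample(shared)
      dp <- db[perm, perm]
      dimnames(dp) <- list(shared, shared)
      null_r[p] <- cor(da[ut], dp[ut])
    }
  })
  list(cophenetic_r = r_obs, rf_distance = rf,
       p = (sum(null_r >= r_obs) + 1) / (n_perm + 1),
       shared_leaves = shared)
}

#' Correlation of CD3-complex expression with total TCR reads
#'
#' x = log10 of the summed TPM of CD3D, CD3G, CD3E and CD247; y = log10 of
#' the summed alpha- plus beta-chain TCR reads; returns the Pearson
#' correlation and p-value across samples.
#'
#' @param tpm genes x samples expression matrix containing the four CD3
#'   genes.
#' @param repertoires named list of clonotype data.frames (names matching
#'   columns of \code{tpm}).
#' @param cd3_genes the four CD3-complex genes.
#' @return list with \code{r}, \code{p}, \code{data} (per-sample x, y).
#' @export
cd3_tcr_correlation <- function(tpm, repertoires,
                                cd3_genes = c("CD3D", "CD3G", "CD3E",
                                              "CD247")) {
  samples <- intersect(colnames(tpm), names(repertoires))
  if (length(samples) < 3) stop("need at least 3 samples with both data types")
  x <- colSums(tpm[cd3_genes, samples, drop = FALSE])
  y <- vapply(repertoires[samples], function(df)
    sum(df$duplicate_count[df$chain %in% c("alpha", "beta")]), 0)
  ok <- x > 0 & y > 0
  if (any(!ok)) {
    warning(sprintf("%d samples with non-positive sums dropped", sum(!ok)))
    x <- x[ok]; y <- y[ok]
  }
  ct <- cor.test(log10(x), log10(y), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       data = data.frame(sample_id = names(x), log10_cd3_tpm = log10(x),
                         log10_tcr_reads = log10(y)))
}
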