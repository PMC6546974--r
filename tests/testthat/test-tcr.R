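test_that("UMI consensus enforces the barcode template and identity rule", {
  umi_ok <- "TACGGTAACGTTGCGT"   # T at 1, 6, 11, 16
  umi_bad <- "AACGGTAACGTTGCGT"  # first base not T
  reads <- data.frame(umi = rep(umi_ok, 3), sequence = rep("ACGTACGT", 3))
  out <- umi_consensus(reads)
  expect_equal(nrow(out), 1)
  expect_identical(out$consensus, "ACGTACGT")
  expect_equal(out$n_reads, 3L)
  # two reads at 50% identity: group discarded
  lowid <- data.frame(umi = rep(umi_ok, 2),
                      sequence = c("AAAAAAAA", "AAAATTTT"))
  expect_equal(nrow(umi_consensus(lowid)), 0)
  # invalid template discarded
  bad <- data.frame(umi = umi_bad, sequence = "ACGT")
  expect_equal(nrow(umi_consensus(bad)), 0)
  # majority vote at high identity
  mv <- data.frame(umi = rep(umi_ok, 3),
                   sequence = c("ACGTACGT", "ACGTACGT", "ACGTACGA"))
  expect_identical(umi_consensus(mv)$consensus, "ACGTACGT")
  expect_equal(nrow(umi_consensus(reads[0, ])), 0)
})

test_that("clone definition groups by CDR3 + V (+J) and conserves reads", {
  rep1 <- toy_repertoire(c("AAATTT", "AAATTT", "CCCGGG"),
                         v = c("TRBV1", "TRBV1", "TRBV2"),
                         counts = c(3L, 2L, 4L))
  cl <- define_clones(rep1)
  expect_equal(nrow(cl), 2)
  expect_equal(sum(cl$size), sum(rep1$duplicate_count))
  expect_equal(cl$size[cl$cdr3_nt == "AAATTT"], 5L)
  # same CDR3, different V: two clones
  rep2 <- toy_repertoire(c("AAATTT", "AAATTT"), v = c("TRBV1", "TRBV2"))
  expect_equal(nrow(define_clones(rep2)), 2)
  # conservation on a generated repertoire
  co <- small_cohort()
  r <- co$cases[[1]]$repertoires[[1]]
  expect_equal(sum(define_clones(r)$size), sum(r$duplicate_count))
})

test_that("public clones are removed across patients and against the database", {
  p1 <- toy_repertoire(c("AAATTT", "CCCGGG"))
  p2 <- toy_repertoire(c("AAATTT", "GGGCCC"))
  db <- toy_repertoire("GGGCCC")
  out <- remove_public(list(pt1 = p1, pt2 = p2), external_db = db)
  expect_identical(out$pt1$cdr3_nt, "CCCGGG")   # shared AAATTT removed
  expect_equal(nrow(out$pt2), 0)                # shared + db hit
  solo <- remove_public(list(pt1 = p1, pt2 = toy_repertoire("TTTAAA")))
  expect_equal(nrow(solo$pt1), 2)
})

test_that("TCR sharing labels follow the all/some/one rule with unit fractions", {
  sites <- list(
    s1 = toy_repertoire(c("AAATTT", "CCCGGG", "TTTCCC"), counts = c(5L, 3L, 2L)),
    s2 = toy_repertoire(c("AAATTT", "CCCGGG"), counts = c(1L, 9L)),
    s3 = toy_repertoire(c("AAATTT", "GGGAAA"), counts = c(4L, 6L)))
  out <- classify_tcr_sharing(sites)
  labs <- out$labels
  key <- function(nt) paste(nt, "TRBV1", "TRBJ1-1", sep = "|")
  expect_identical(unname(labs[key("AAATTT")]), "stem")
  expect_identical(unname(labs[key("CCCGGG")]), "clade")
  expect_identical(unname(labs[key("TTTCCC")]), "private")
  expect_equal(unname(rowSums(out$site_fractions)), rep(1, 3))
  expect_error(classify_tcr_sharing(sites[1]), "single site")
})

test_that("Gini matches the brute-force mean-absolute-difference formula", {
  expect_equal(gini_index(rep(7, 10)), 0)
  expect_equal(gini_index(c(999, 1)), gini_brute(c(999, 1)))
  set.seed(4)
  for (i in 1:20) {
    x <- rpois(sample(3:40, 1), 5)
    expect_equal(gini_index(x), gini_brute(x))
  }
  expect_error(gini_index(c(-1, 2)), "non-negative")
})

test_that("subsampled clonality is seeded, stable and correctly scaled", {
  co <- small_cohort()
  r <- co$cases[[1]]$repertoires[[3]]
  a <- subsampled_clonality(r, depth = 1000, repeats = 10, seed = 5)
  b <- subsampled_clonality(r, depth = 1000, repeats = 10, seed = 5)
  expect_identical(a, b)
  expect_error(subsampled_clonality(r, depth = 5), "at least 10")
  tiny <- toy_repertoire("AAATTT", counts = 50L)
  expect_warning(expect_null(
    subsampled_clonality(tiny, depth = 1000)), "excluded")
  # one clone with 150 of 1000 reads: LCS (read-percentage dialect) = 15
  even <- toy_repertoire(replicate(86, paste(sample(c("A","C","G","T"), 12,
                                                    replace = TRUE),
                                             collapse = "")),
                         counts = c(150L, rep(10L, 85)))
  out <- subsampled_clonality(even, depth = 1000, repeats = 1, seed = 1)
  expect_equal(out$lcs_pct_reads, 15, tolerance = 0.2)
  # doubling repeats (extending the same subsample stream) moves the mean
  # Gini by less than 3 replicate SEs
  m1 <- subsampled_clonality(r, depth = 1000, repeats = 10, seed = 2)
  m2 <- subsampled_clonality(r, depth = 1000, repeats = 20, seed = 2)
  with_seed <- mima:::with_seed
  g <- with_seed(11, replicate(10, subsampled_clonality(
    r, depth = 1000, repeats = 1,
    seed = sample.int(1e6, 1))$gini_vertex))
  se <- sd(g) / sqrt(10)
  expect_lt(abs(m1$gini_vertex - m2$gini_vertex), 3 * se + 1e-12)
})

test_that("overlap coefficient follows the printed formula and is symmetric", {
  # C_i = 10, C_j = 30, C_ij = 5 -> O = 5 / 20 = 0.25
  mk <- function(n, prefix) toy_repertoire(
    paste0(prefix, sprintf("%03d", seq_len(n)), "AAA"))
  shared <- mk(5, "SH")
  ri <- rbind(shared, mk(5, "II"))
  rj <- rbind(shared, mk(25, "JJ"))
  expect_equal(overlap_coefficient(ri, rj, depth = NULL), 0.25)
  ident <- mk(12, "QQ")
  expect_equal(overlap_coefficient(ident, ident, depth = NULL), 1)
  expect_equal(overlap_coefficient(mk(4, "AA"), mk(4, "BB"), depth = NULL), 0)
  # symmetry and range under subsampling
  co <- small_cohort()
  reps <- co$cases[[1]]$repertoires
  o12 <- overlap_coefficient(reps[[1]], reps[[2]], depth = 500,
                             repeats = 5, seed = 9)
  o21 <- overlap_coefficient(reps[[2]], reps[[1]], depth = 500,
                             repeats = 5, seed = 9)
  expect_gte(o12, 0); expect_lte(o12, 1)
  expect_lt(abs(o12 - o21), 0.05)
  expect_true(is.na(overlap_coefficient(toy_repertoire("AAA", counts = 3L),
                                        reps[[1]], depth = 500)))
})

test_that("random-pair overlap equals direct set arithmetic", {
  set.seed(8)
  pool <- replicate(60, paste(sample(c("A", "C", "G", "T"), 12,
                                     replace = TRUE), collapse = ""))
  for (i in 1:200) {
    a <- toy_repertoire(sample(pool, sample(5:40, 1)))
    b <- toy_repertoire(sample(pool, sample(5:40, 1)))
    got <- overlap_coefficient(a, b, depth = NULL)
    ca <- unique(a$cdr3_nt); cb <- unique(b$cdr3_nt)
    expect_equal(got, length(intersect(ca, cb)) /
                   (0.5 * (length(ca) + length(cb))))
  }
})

test_that("Jaccard similarity, clustering and metric property hold", {
  r1 <- toy_repertoire(c("AAATTTGGG", "CCCGGGTTT", "TTTCCCAAA"))
  r1$cdr3_aa <- c("A", "B", "C")
  r2 <- r1; r2$cdr3_aa <- c("B", "C", "D")
  out <- jaccard_tree(list(s1 = r1, s2 = r2))
  expect_equal(out$similarity["s1", "s2"], 0.5)  # {A,B,C} vs {B,C,D}
  expect_null(out$tree)
  ident <- jaccard_tree(list(a = r1, b = r1, c = r1))
  expect_equal(unname(ident$similarity), matrix(1, 3, 3))
  expect_true(all(ape::cophenetic.phylo(ident$tree) == 0))
  # triangle inequality for Jaccard distance on generated repertoires
  co <- small_cohort()
  sim <- jaccard_tree(co$cases[[1]]$repertoires)$similarity
  d <- 1 - sim
  n <- nrow(d)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
})

test_that("tree concordance is exact for self-comparison and matches oracles", {
  skip_if_not_installed("igraph")
  co <- small_cohort()
  tr <- co$cases[[1]]$tree
  self <- tree_concordance(tr, tr, n_perm = 50, seed = 1)
  expect_equal(self$cophenetic_r, 1)
  expect_equal(self$rf_distance, 0)
  # path-sum distances equal all-pairs shortest paths on the tree graph
  d_ape <- ape::cophenetic.phylo(tr)
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tr$edge.length
  tips <- as.character(seq_along(tr$tip.label))
  d_ig <- igraph::distances(g, v = tips, to = tips)
  dimnames(d_ig) <- list(tr$tip.label, tr$tip.label)
  expect_equal(d_ape[rownames(d_ig), colnames(d_ig)], d_ig,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("caterpillar against its mirror matches hand-enumerated RF", {
  # caterpillar (((((a,b),c),d),e),f) vs mirror over reversed leaf order
  t1 <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  t2 <- ape::read.tree(text = "(((((f,e),d),c),b),a);")
  t1$edge.length <- rep(1, nrow(t1$edge))
  t2$edge.length <- rep(1, nrow(t2$edge))
  out <- tree_concordance(t1, t2, n_perm = 20, seed = 1)
  # unrooted splits of t1: ab|cdef, abc|def, abcd|ef; t2 unrooted has the
  # same splits (mirroring does not change the split set) -> RF = 0
  expect_equal(out$rf_distance, 0)
  t3 <- ape::read.tree(text = "(((((a,c),e),b),d),f);")
  t3$edge.length <- rep(1, nrow(t3$edge))
  out2 <- tree_concordance(t1, t3, n_perm = 20, seed = 1)
  # splits of t3: ace|bdf, ac|bdef, aceb|df; none match t1's -> RF = 6
  expect_equal(out2$rf_distance, 6)
})

test_that("organ permutation test is powered, structured and sized correctly", {
  cfg <- cohort_config(n_cases = 1, metastases_range = c(8, 8),
                       n_clades = 3, stem_mean = 20, clade_mean = 10,
                       private_mean = 4, tcr_clones_per_site = 60,
                       tcr_shared_clade = 0.35, tcr_shared_stem = 0.05,
                       cells_per_sample = 60, organ_mode = "clade",
                       seed = 2)
  co <- generate_cohort(cfg)
  cs <- co$cases[[1]]
  out <- permutation_organ_test(cs$repertoires, cs$organ, n_perm = 40,
                                seed = 3)
  expect_length(out$null, 40)
  expect_length(out$null_rf, 40)
  expect_lte(out$p_organ, 0.05)
  expect_lte(out$p_structure, 0.1)
  expect_error(permutation_organ_test(cs$repertoires[1:3], cs$organ),
               "4 samples")
  one_organ <- setNames(rep("liver", length(cs$organ)), names(cs$organ))
  expect_error(permutation_organ_test(cs$repertoires, one_organ),
               "2 organs")
})

test_that("CD3 expression tracks total TCR reads", {
  co <- small_cohort()
  rs <- vapply(co$cases, function(cs)
    cd3_tcr_correlation(cs$tpm, cs$repertoires)$r, 0)
  # immune-rich metastases carry both more CD3 transcript and more reads
  expect_true(all(rs > 0))
  expect_gt(mean(rs), 0.4)
  # exact proportionality gives r = 1
  tpm <- matrix(10^(seq(0.5, 3, length.out = 6)), 4, 6, byrow = TRUE,
                dimnames = list(c("CD3D", "CD3G", "CD3E", "CD247"),
                                paste0("s", 1:6)))
  reps <- lapply(colSums(tpm), function(tot)
    toy_repertoire("AAATTT", counts = as.integer(round(tot * 3))))
  names(reps) <- colnames(tpm)
  exact <- cd3_tcr_correlation(tpm, reps)
  expect_equal(exact$r, 1, tolerance = 1e-6)
  # invariance to sample order
  perm <- cd3_tcr_correlation(tpm[, 6:1], reps)
  expect_equal(perm$r, exact$r)
  expect_error(cd3_tcr_correlation(tpm[, 1:2], reps[1:2]), "3 samples")
})
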