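test_that("gene rates normalise counts and reject empty catalogs", {
  expect_equal(unname(build_gene_rates(c(g1 = 2, g2 = 8))), c(0.2, 0.8))
  expect_equal(unname(build_gene_rates(c(solo = 7))), 1)
  expect_error(build_gene_rates(c(a = 0, b = 0)), "no mutations")
  set.seed(1)
  r <- build_gene_rates(setNames(rpois(50, 20) + 1, paste0("g", 1:50)))
  expect_equal(sum(r), 1)
})

test_that("the toy binding predicate is deterministic with the configured rate", {
  pred <- hash_binder(0.05)
  peps <- replicate(4000, paste(sample(LETTERS[1:20], 9, replace = TRUE),
                                collapse = ""))
  ic1 <- pred(peps, "HLA-A*S01")
  ic2 <- pred(peps, "HLA-A*S01")
  expect_identical(ic1, ic2)
  expect_true(all(ic1 > 0))
  # empirical binder fraction approximates the configured rate
  expect_lt(abs(mean(ic1 <= 500) - 0.05), 0.015)
  # different alleles give different binder sets
  ic3 <- pred(peps, "HLA-B*S09")
  expect_false(identical(ic1 <= 500, ic3 <= 500))
})

test_that("simulated mutation sets preserve contexts and follow gene rates", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  rates <- build_gene_rates(co$reference_catalog)
  mut <- cs$mutations[1:50, ]
  sim <- simulate_mutation_set(mut, rates, co$gene_model, seed = 3)
  expect_equal(nrow(sim), 50)
  # hard invariant: pyrimidine-context multiset preserved
  expect_identical(sort(mima:::pyr_context3(sim$context)$context),
                   sort(mima:::pyr_context3(mut$context)$context))
  # substitution channel preserved
  expect_identical(channel_of(sim$ref, sim$alt, sim$context),
                   channel_of(mut$ref, mut$alt, mut$context))
  expect_identical(sim, simulate_mutation_set(mut, rates, co$gene_model,
                                              seed = 3))

  # two genes with rates 0.2 / 0.8: assignment frequencies follow rates
  gm <- co$gene_model
  two <- c(gm$gene[1], gm$gene[2])
  r2 <- setNames(c(0.2, 0.8), two)
  one <- mut[rep(1, 10000), ]
  sim2 <- simulate_mutation_set(one, r2, gm, seed = 9)
  frac <- mean(sim2$gene == two[2])
  expect_lt(abs(frac - 0.8), 0.02)
})

test_that("candidate peptide enumeration matches the windowing rules", {
  prot <- paste(rep("A", 200), collapse = "")
  # centre of a 17-mer window: nine 9-mers cover the mutant residue
  p50 <- enumerate_candidate_peptides(prot, 50, "V", window = 17)
  expect_equal(nrow(p50), 9)
  expect_true(all(substr(p50$mutant, 50 - p50$start + 1,
                         50 - p50$start + 1) == "V"))
  # boundary truncation: position 1 leaves a single window
  p1 <- enumerate_candidate_peptides(prot, 1, "V", window = 17)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$start, 1)
  # every mutant 9-mer differs from its wild-type pair at exactly one site
  for (k in seq_len(nrow(p50))) {
    d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                     strsplit(b, "")[[1]]),
                p50$mutant[k], p50$wildtype[k])
    expect_equal(unname(d), 1)
  }
  expect_error(enumerate_candidate_peptides(prot, 10, "*"), "missense")
  expect_error(enumerate_candidate_peptides("SHORT", 2, "V"), "9")
})

test_that("vectorised binder scan equals the per-mutation enumeration", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  gm <- co$gene_model
  pred <- hash_binder(0.2)
  mut <- cs$mutations[1:40, ]
  fast <- mima:::mutations_bind_any(mut, gm, cs$hla, pred)
  slow <- vapply(seq_len(nrow(mut)), function(i) {
    if (mut$effect[i] != "missense") return(FALSE)
    peps <- enumerate_candidate_peptides(gm$protein[[mut$gene[i]]],
                                         mut$aa_pos[i], mut$aa_alt[i])
    any(outer(peps$mutant, cs$hla,
              function(p, a) pred(p, a)) <= 500)
  }, TRUE)
  expect_identical(fast, slow)
})

test_that("neo-epitope counting applies binding and expression rules", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  gm <- co$gene_model
  mis <- cs$mutations[cs$mutations$effect == "missense", ][1:10, ]
  none <- function(p, a) rep(50000, max(length(p), length(a)))
  all_bind <- function(p, a) rep(10, max(length(p), length(a)))
  expect_equal(count_neoepitopes(mis, gm, cs$hla, none)$count, 0)
  # every mutation binds via many 9-mers but counts once
  expect_equal(count_neoepitopes(mis, gm, cs$hla, all_bind)$count, 10)
  # RPKM <= 1 excludes a binder
  expr <- data.frame(gene = mis$gene,
                     gene_rpkm = c(0.5, rep(10, 9)),
                     transcript_rpkm = rep(10, 10))
  expect_equal(count_neoepitopes(mis, gm, cs$hla, all_bind,
                                 expression = expr[!duplicated(expr$gene), ]
  )$count,
  sum(tapply(expr$gene_rpkm, mis$gene, head, 1)[mis$gene] > 1))
})

test_that("empirical p follows the (k+1)/(n+1) convention", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  rates <- build_gene_rates(co$reference_catalog)
  mut <- cs$mutations[cs$presence[, 1], ]
  # a predicate that accepts nothing: observed = expected = 0,
  # every ratio is 1 by convention, p = 101/101 = 1
  none <- function(p, a) rep(50000, max(length(p), length(a)))
  t0 <- observed_expected_test(mut, rates, co$gene_model, cs$hla, none,
                               n_replicates = 100, seed = 1)
  expect_equal(t0$observed, 0)
  expect_true(all(t0$expected == 0))
  expect_true(all(t0$ratios == 1))
  expect_equal(t0$empirical_p, 1)
  expect_error(observed_expected_test(mut, rates, co$gene_model, cs$hla,
                                      none, n_replicates = 5), "10")
  # ratio conventions
  expect_equal(mima:::ratio_with_conventions(3, 0), Inf)
  expect_equal(mima:::ratio_with_conventions(0, 0), 1)
  expect_equal(mima:::ratio_with_conventions(2, 4), 0.5)
})

test_that("a depletion-thinned sample yields p = 1/101 with all ratios below one", {
  cfg <- cohort_config(n_cases = 1, metastases_range = c(2, 2),
                       n_clades = 2, stem_mean = 120, clade_mean = 0,
                       private_mean = 15, tcr_clones_per_site = 10,
                       cells_per_sample = 60, depletion_strength = 0.15,
                       seed = 23)
  co <- generate_cohort(cfg)
  cs <- co$cases[[1]]
  rates <- build_gene_rates(co$reference_catalog)
  tt <- observed_expected_test(cs$mutations[cs$presence[, 1], ], rates,
                               co$gene_model, cs$hla,
                               hash_binder(cfg$binder_rate),
                               n_replicates = 100, seed = 1)
  expect_true(all(tt$ratios < 1))
  expect_equal(tt$empirical_p, 1 / 101)
  expect_lte(tt$empirical_p, 0.01)
})

test_that("stronger depletion weakly decreases the empirical p at fixed seed", {
  ps <- vapply(c(1, 0.5, 0.15), function(ds) {
    cfg <- cohort_config(n_cases = 1, metastases_range = c(2, 2),
                         n_clades = 2, stem_mean = 100, clade_mean = 0,
                         private_mean = 10, tcr_clones_per_site = 10,
                         cells_per_sample = 60, depletion_strength = ds,
                         seed = 31)
    co <- generate_cohort(cfg)
    cs <- co$cases[[1]]
    rates <- build_gene_rates(co$reference_catalog)
    observed_expected_test(cs$mutations[cs$presence[, 1], ], rates,
                           co$gene_model, cs$hla,
                           hash_binder(cfg$binder_rate),
                           n_replicates = 50, seed = 2)$empirical_p
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("the grouped null returns the advertised structure and delegates singletons", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  rates <- build_gene_rates(co$reference_catalog)
  pred <- hash_binder(0.01)
  samples <- lapply(cs$sample_id[1:2], function(s)
    list(mutations = cs$mutations[cs$presence[, s], ][1:40, ],
         alleles = cs$hla))
  out <- grouped_mean_ratio_null(samples, rates, co$gene_model, pred,
                                 n_outer = 5, n_inner = 20, seed = 1)
  expect_length(out$null_means, 5)
  expect_true(out$p > 0 && out$p <= 1)
  expect_length(out$per_sample, 2)
  single <- grouped_mean_ratio_null(samples[1], rates, co$gene_model,
                                    pred, n_outer = 5, n_inner = 20,
                                    seed = 1)
  expect_s3_class(single, "neoepitope_test")
})

test_that("HLA LOH calls require both thresholds and track restricted neo-epitopes", {
  tab <- data.frame(allele = c("A1", "A2", "B1", "B2"),
                    copy_number = c(0.4, 0.6, 0.4, 1.1),
                    p_value = c(0.01, 0.01, 0.2, 0.5))
  out <- hla_loh_assess(tab)
  expect_equal(out$calls$lost, c(TRUE, FALSE, FALSE, FALSE))
  # 2 of 4 neo-epitopes bind only lost alleles
  nb <- list(n1 = "A1", n2 = c("A1"), n3 = c("A1", "A2"), n4 = "B2")
  out2 <- hla_loh_assess(tab, nb)
  expect_equal(out2$fraction_lost_restricted, 0.5)
  expect_warning(hla_loh_assess(tab, list(nx = "Z9")), "skipped")
})
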