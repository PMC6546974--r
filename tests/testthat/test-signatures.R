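test_that("profile construction counts, collapses and rejects correctly", {
  one <- data.frame(ref = "C", alt = "A", context = "ACA")
  p <- build_profile96(one)
  expect_equal(unname(p["A[C>A]A"]), 1L)
  expect_equal(sum(p), 1L)
  # purine-strand record collapses to the same channel
  rc <- data.frame(ref = "G", alt = "T", context = "TGT")
  expect_equal(unname(build_profile96(rc)["A[C>A]A"]), 1L)
  # conservation: channel sum equals number of valid substitutions
  co <- small_cohort()
  mut <- co$cases[[1]]$mutations
  expect_equal(sum(build_profile96(mut)), nrow(mut))
  # context mismatch rejected with reason
  bad <- data.frame(ref = "C", alt = "A", context = "ATA")
  pb <- build_profile96(bad)
  expect_equal(sum(pb), 0L)
  expect_length(attr(pb, "rejected"), 1)
})

test_that("profile entropy matches analytic limits and is permutation-invariant", {
  single <- setNames(c(100, rep(0, 95)), channel_labels())
  expect_equal(profile_entropy(single), 0)
  uniform <- setNames(rep(5, 96), channel_labels())
  expect_equal(profile_entropy(uniform), log(96))
  two <- setNames(c(7, 7, rep(0, 94)), channel_labels())
  expect_equal(profile_entropy(two), log(2))
  set.seed(2)
  x <- rpois(96, 3)
  expect_equal(profile_entropy(x), profile_entropy(sample(x)))
  expect_error(profile_entropy(rep(0, 96)), "empty")
})

test_that("cosine matching equals brute-force dot products", {
  S <- synthetic_signature_catalog(5, seed = 4)
  hit <- cosine_match(S[, 3], S)
  expect_identical(hit$label, colnames(S)[3])
  expect_equal(hit$similarity, 1)
  set.seed(9)
  for (i in 1:20) {
    v <- runif(96)
    got <- cosine_match(v, S)
    sims <- vapply(seq_len(ncol(S)), function(k)
      sum(v * S[, k]) / sqrt(sum(v^2) * sum(S[, k]^2)), 0)
    expect_equal(unname(got$similarities), sims)
    expect_identical(got$label, colnames(S)[which.max(sims)])
  }
  expect_error(cosine_match(rep(0, 96), S), "zero")
})

test_that("NNLS agrees with an independent quadratic-programming solver", {
  skip_if_not_installed("pracma")
  set.seed(6)
  for (i in 1:25) {
    A <- matrix(runif(96 * 5), 96, 5)
    b <- runif(96, 0, 10)
    mine <- mima:::nnls_fit(A, b)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("exact mixtures are recovered to numerical precision", {
  S <- synthetic_signature_catalog(4, seed = 4)
  m <- 1000 * (0.6 * S[, 1] + 0.4 * S[, 2])
  fit <- fit_exposures(m, S, attribution = FALSE)
  expect_equal(unname(fit$exposures),
               c(600, 400, 0, 0), tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # single-signature profile: full total on that signature
  fit2 <- fit_exposures(500 * S[, 3], S)
  expect_equal(unname(fit2$exposures[3]), 500, tolerance = 1e-6)
  expect_equal(unname(fit2$exposures[-3]), rep(0, 3), tolerance = 1e-6)
})

test_that("attribution threshold drops weak signatures and refits", {
  S <- synthetic_signature_catalog(3, seed = 8)
  # 1000 mutations: threshold max(30, 10) = 30; plant exposure 20 < 30
  m <- 980 * S[, 1] + 20 * S[, 2]
  fit <- fit_exposures(m, S, attribution = TRUE)
  expect_false(colnames(S)[2] %in% fit$attributed)
  expect_true(colnames(S)[1] %in% fit$attributed)
  expect_equal(unname(fit$exposures[2]), 0)
  # min() dialect keeps it (threshold min(30, 10) = 10 < 20)
  fit_min <- fit_exposures(m, S, threshold_rule = "min")
  expect_true(colnames(S)[2] %in% fit_min$attributed)
  # nothing survives: all-zero exposures, rmse = rms(m), flagged
  tiny <- 5 * S[, 1]
  fit0 <- fit_exposures(tiny, S, attribution = TRUE)
  expect_true(fit0$all_dropped)
  expect_equal(fit0$rmse, sqrt(mean((5 * S[, 1])^2)))
})

test_that("rmse responds to adding or removing a truly present signature", {
  S <- synthetic_signature_catalog(4, seed = 12)
  m <- 400 * S[, 1] + 300 * S[, 2] + 300 * S[, 3]
  full <- fit_exposures(m, S[, 1:3], attribution = FALSE)
  missing <- fit_exposures(m, S[, 1:2], attribution = FALSE)
  expect_lt(full$rmse, missing$rmse)
  extra <- fit_exposures(m, S, attribution = FALSE)
  expect_lte(extra$rmse, full$rmse + 1e-9)
})

test_that("KL-NMF error is monotone and rank-1 recovers the common profile", {
  set.seed(5)
  base <- runif(96, 0.1, 1)
  V <- matrix(rep(base * 100, 6), 96, 6)
  fit <- mima:::kl_nmf(V, 1, max_iter = 200)
  expect_true(all(diff(fit$kl_trace) <= 1e-8))
  expect_gt(sum(fit$W[, 1] * base) /
              sqrt(sum(fit$W[, 1]^2) * sum(base^2)), 0.9999)
})

test_that("planted signatures are recovered by bootstrapped NMF", {
  S <- synthetic_signature_catalog(3, seed = 31)
  set.seed(31)
  n <- 120
  E <- matrix(rgamma(3 * n, 2, 0.01), 3, n)  # exposures ~ hundreds
  V <- matrix(0, 96, n)
  for (j in seq_len(n))
    V[, j] <- rpois(96, S %*% E[, j])
  res <- nmf_extract(V, rank_range = 3, n_bootstrap = 8, seed = 2,
                     max_iter = 150)
  W <- res[["3"]]$signatures
  best <- apply(W, 2, function(w) max(apply(S, 2, function(s)
    sum(w * s) / sqrt(sum(w^2) * sum(s^2)))))
  expect_true(all(best >= 0.90))
  expect_error(nmf_extract(V[, 1:2], rank_range = 3), "rank")
})

test_that("bootstrap profile similarity behaves at the identity and disjoint limits", {
  a <- setNames(c(rep(50, 10), rep(0, 86)), channel_labels())
  b <- setNames(c(rep(0, 86), rep(50, 10)), channel_labels())
  same <- bootstrap_profile_similarity(a, a, n_boot = 500, seed = 1)
  expect_equal(same$cosine, 1)
  # the observed cosine sits above the whole label-swap null
  expect_lte(same$p, 0.05)
  disj <- bootstrap_profile_similarity(a, b, n_boot = 500, seed = 1)
  expect_equal(disj$cosine, 0)
  # disjoint profiles are far less similar than the pooled null allows
  expect_gt(disj$p, 0.5)
  # bootstrap spread shrinks as totals grow
  sm <- bootstrap_profile_similarity(a, a * 1, n_boot = 300, seed = 2)
  lg <- bootstrap_profile_similarity(a * 100, a * 100, n_boot = 300,
                                     seed = 2)
  expect_lt(sd(lg$boot_cosines), sd(sm$boot_cosines))
  expect_warning(bootstrap_profile_similarity(a, b, n_boot = 50, seed = 1),
                 "coarse")
})

test_that("stratified profiles conserve channel counts and planted structure", {
  co <- small_cohort()
  cs <- co$cases[[1]]
  lin <- setNames(cs$mutations$lineage, cs$mutations$mutation_id)
  strat <- stratified_profiles(cs$mutations, lin)
  expect_equal(as.numeric(strat$stem) + as.numeric(strat$clade) +
                 as.numeric(strat$private), as.numeric(strat$all))
  # empty stratum gives an all-zero profile
  only_stem <- cs$mutations[lin == "stem", ]
  s2 <- stratified_profiles(only_stem, lin[lin == "stem"])
  expect_equal(sum(s2$private), 0L)
})

test_that("a signature planted on the stem branch is found in the stem profile", {
  S <- synthetic_signature_catalog(4, seed = 99)
  cfg <- cohort_config(n_cases = 1, metastases_range = c(5, 5),
                       stem_mean = 800, clade_mean = 50, private_mean = 50,
                       signature_mixture = c(SBS_S1 = 1, SBS_S2 = 0,
                                             SBS_S3 = 0, SBS_S4 = 0),
                       signature_catalog = S,
                       tcr_clones_per_site = 10, cells_per_sample = 60,
                       seed = 17)
  co <- generate_cohort(cfg)
  cs <- co$cases[[1]]
  lin <- setNames(cs$mutations$lineage, cs$mutations$mutation_id)
  strat <- stratified_profiles(cs$mutations, lin)
  stem_match <- cosine_match(as.numeric(strat$stem) + 1e-9, S)
  expect_identical(stem_match$label, "SBS_S1")
  expect_gt(stem_match$similarity, 0.95)
})
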