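# Shared fixtures, built once per test run.

# A small but complete cohort exercising every downstream module.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_cases = 2, metastases_range = c(5, 8),
                           stem_mean = 80, clade_mean = 50,
                           private_mean = 15, tcr_clones_per_site = 60,
                           cells_per_sample = 200, seed = 7)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# deterministic toy clonotype table
toy_repertoire <- function(cdr3, v = "TRBV1", j = "TRBJ1-1",
                           counts = rep(1L, length(cdr3)),
                           chain = "beta", sample_id = "S1") {
  data.frame(sample_id = sample_id, chain = chain, v_call = v, j_call = j,
             cdr3_nt = cdr3,
             cdr3_aa = substr(cdr3, 1, max(1, nchar(cdr3) %/% 3)),
             duplicate_count = counts, stringsAsFactors = FALSE)
}

# brute-force Gini by the double-sum mean-absolute-difference formula
gini_brute <- function(x) {
  n <- length(x)
  if (n == 0 || mean(x) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}
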