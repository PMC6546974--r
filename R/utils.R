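# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  force(seed)  # evaluate before saving state: seed may itself be a draw
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream seed from a master seed and an index; kept below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_config(field, "must be a fraction in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x)))
    stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(x)
}

# Deterministic string hash -> uniform(0,1).  Used only by the toy binding
# predicate; all strings hashed are short (9-mer peptides, allele names).
# FNV-style accumulation kept in exact double range, final LCG scramble.
hash_unit <- function(strings) {
  n <- length(strings)
  if (n == 0L) return(numeric(0))
  nc <- nchar(strings)
  w <- max(nc)
  if (any(nc < w)) strings <- formatC(strings, width = w, flag = "-")
  codes <- utf8ToInt(paste(strings, collapse = ""))
  m <- matrix(codes, nrow = w, ncol = n)
  h <- rep(2166136261 %% 2147483647, n)
  for (i in seq_len(nrow(m))) {
    h <- (h * 127 + m[i, ] * (i + 16)) %% 2147483647
  }
  h <- (h * 48271) %% 2147483647
  h <- (h * 69621) %% 2147483647
  h / 2147483647
}

# Pearson-style cosine similarity between two non-negative vectors.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
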