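#' Build a 96-channel mutational profile
#'
#' Counts substitutions into the 96 pyrimidine-centred channels
#' (\code{\link{channel_labels}}).  Purine-reference mutations are collapsed
#' by reverse-complementing ref, alt and context.  Records whose context
#' middle base does not equal the reference base (or with ref == alt) are
#' rejected and reported.
#'
#' @param mutations data.frame with columns \code{ref}, \code{alt},
#'   \code{context} (reference-strand trinucleotide).  Only single-base
#'   substitutions are counted; other rows are rejected.
#' @return object of class \code{profile96}: named integer vector of
#'   length 96 with attributes \code{total} and \code{rejected}.
#' @export
build_profile96 <- function(mutations) {
  if (nrow(mutations) == 0) {
    p <- setNames(integer(96), CHANNELS)
    return(structure(p, total = 0L, rejected = character(0),
                     class = "profile96"))
  }
  is_snv <- nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1 &
    mutations$ref %in% DNA_BASES & mutations$alt %in% DNA_BASES
  ch <- rep(NA_character_, nrow(mutations))
  ch[is_snv] <- channel_of(mutations$ref[is_snv], mutations$alt[is_snv],
                           mutations$context[is_snv])
  rejected <- which(is.na(ch))
  counts <- table(factor(ch[!is.na(ch)], levels = CHANNELS))
  p <- setNames(as.integer(counts), CHANNELS)
  structure(p, total = sum(p),
            rejected = if (length(rejected))
              sprintf("row %d: invalid substitution/context", rejected)
            else character(0),
            class = "profile96")
}

#' @export
print.profile96 <- function(x, ...) {
  cat(sprintf("profile96: %d mutations over %d occupied channels\n",
              attr(x, "total"), sum(x > 0)))
  invisible(x)
}

as_profile_vector <- function(profile) {
  if (inherits(profile, "profile96")) as.numeric(profile)
  else {
    stopifnot(length(profile) == 96)
    as.numeric(profile)
  }
}

#' Shannon entropy of a normalised mutational profile
#'
#' H = -sum p_i log p_i (natural log) over occupied channels,
#' p = counts / total.  Uniform mass over the 96 channels gives log(96).
#'
#' @param profile a \code{profile96} or 96-vector of non-negative counts.
#' @return non-negative entropy in nats.
#' @export
profile_entropy <- function(profile) {
  p <- as_profile_vector(profile)
  tot <- sum(p)
  if (tot <= 0) stop("entropy undefined for an empty profile")
  p <- p[p > 0] / tot
  -sum(p * log(p))
}

#' Best cosine match against a signature catalog
#'
#' @param sig 96-vector.
#' @param catalog 96 x K matrix with column names.
#' @return list with \code{label} and \code{similarity}; also the full
#'   similarity vector.
#' @export
cosine_match <- function(sig, catalog) {
  sig <- as_profile_vector(sig)
  if (sum(sig^2) == 0) stop("cosine match undefined for zero vector")
  sims <- apply(catalog, 2, function(col) cosine_sim(sig, col))
  best <- which.max(sims)
  list(label = colnames(catalog)[best], similarity = unname(sims[best]),
       similarities = sims)
}

# Lawson-Hanson non-negative least squares: min ||A x - b||^2, x >= 0.
# A is 96 x K with K small; the active-set loop converges in a few passes.
nnls_fit <- function(A, b, tol = 1e-10) {
  K <- ncol(A)
  x <- numeric(K)
  passive <- rep(FALSE, K)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30 * K) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(K)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves min ||m - S e||^2 with e >= 0 where m is the 96-channel profile
#' (in mutation counts) and S the catalog.  With \code{attribution = TRUE},
#' signatures whose exposure falls below the attribution threshold --
#' by default max(3\% of the sample total, 10 mutations); set
#' \code{threshold_rule = "min"} for min(3\%, 10) -- are removed and the
#' fit re-solved on the survivors, iterating until stable.
#'
#' @param profile \code{profile96} or 96-vector of counts.
#' @param signatures 96 x K catalog matrix (columns sum to 1).
#' @param attribution apply the attribution threshold.
#' @param threshold_rule \code{"max"} or \code{"min"} combination of the
#'   3\%-of-total and 10-mutation floors.
#' @return object of class \code{exposure_fit}: list with \code{exposures}
#'   (named, mutation units), \code{fitted}, \code{residuals}
#'   (m - S e), \code{rmse}, \code{attributed}, \code{all_dropped}.
#' @export
fit_exposures <- function(profile, signatures, attribution = TRUE,
                          threshold_rule = c("max", "min")) {
  threshold_rule <- match.arg(threshold_rule)
  m <- as_profile_vector(profile)
  total <- sum(m)
  if (total <= 0) stop("profile total must be positive")
  S <- as.matrix(signatures)
  labels <- colnames(S)
  thr <- if (threshold_rule == "max") max(0.03 * total, 10)
         else min(0.03 * total, 10)

  active <- rep(TRUE, ncol(S))
  e <- numeric(ncol(S))
  e[active] <- nnls_fit(S, m)
  if (attribution) {
    repeat {
      drop <- active & e < thr
      if (!any(drop)) break
      active <- active & !drop
      e <- numeric(ncol(S))
      if (!any(active)) break
      e[active] <- nnls_fit(S[, active, drop = FALSE], m)
    }
  }
  if (!any(active)) {
    fitted <- numeric(96)
    r <- m - fitted
    return(structure(list(exposures = setNames(numeric(ncol(S)), labels),
                          fitted = fitted, residuals = r,
                          rmse = sqrt(mean(r^2)),
                          attributed = character(0), all_dropped = TRUE),
                     class = "exposure_fit"))
  }
  e_full <- setNames(numeric(ncol(S)), labels)
  e_full[active] <- e[active]
  fitted <- as.numeric(S %*% e_full)
  r <- m - fitted
  structure(list(exposures = e_full, fitted = fitted, residuals = r,
                 rmse = sqrt(mean(r^2)),
                 attributed = labels[active], all_dropped = FALSE),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("exposure_fit\n")
  print(round(x$exposures, 2))
  cat(sprintf("rmse: %.4f; attributed: %s\n", x$rmse,
              paste(x$attributed, collapse = ", ")))
  invisible(x)
}

# one KL-NMF run (multiplicative updates, Lee & Seung divergence form)
kl_nmf <- function(V, rank, max_iter = 200, tol = 1e-6) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  eps <- 1e-12
  kl_div <- function(V, WH)
    sum(V * log((V + eps) / (WH + eps)) - V + WH)
  WH <- W %*% H
  err <- kl_div(V, WH)
  errs <- err
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% (V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) /
      matrix(rowSums(H), n, rank, byrow = TRUE)
    WH <- W %*% H
    new_err <- kl_div(V, WH)
    errs <- c(errs, new_err)
    if (abs(err - new_err) <= tol * abs(err)) break
    err <- new_err
  }
  # normalise signature columns to sum 1, push scale into H
  cs <- colSums(W)
  W <- sweep(W, 2, cs, `/`)
  H <- sweep(H, 1, cs, `*`)
  list(W = W, H = H, kl = err, kl_trace = errs)
}

#' Extract candidate signatures by bootstrapped KL-divergence NMF
#'
#' Multiplicative-update NMF minimising the generalised Kullback-Leibler
#' divergence, run on bootstrap resamples of the sample set.  Bootstrap
#' signatures are pooled per rank and clustered greedily at cosine >= 0.8;
#' cluster means (renormalised) are the consensus signatures.
#'
#' @param profiles list of \code{profile96} (or a 96 x n matrix).
#' @param rank_range integer vector of ranks to try.
#' @param n_bootstrap bootstrap resamples per rank.
#' @param seed integer seed.
#' @param max_iter,tol NMF iteration controls.
#' @return list per rank: \code{signatures} (96 x r consensus matrix),
#'   \code{mean_kl}, \code{stability} (cluster sizes / n_bootstrap).
#' @export
nmf_extract <- function(profiles, rank_range = 2:4, n_bootstrap = 20,
                        seed = 1, max_iter = 200, tol = 1e-6) {
  V <- if (is.matrix(profiles)) profiles
       else do.call(cbind, lapply(profiles, as_profile_vector))
  if (any(colSums(V) <= 0)) stop("all profiles must have positive totals")
  if (max(rank_range) > ncol(V))
    stop("rank exceeds the number of samples")
  with_seed(seed, {
    out <- list()
    for (r in rank_range) {
      sigs <- list()
      kls <- numeric(n_bootstrap)
      for (b in seq_len(n_bootstrap)) {
        cols <- sample(ncol(V), ncol(V), replace = TRUE)
        fit <- kl_nmf(V[, cols, drop = FALSE], r, max_iter, tol)
        sigs[[b]] <- fit$W
        kls[b] <- fit$kl
      }
      pool <- do.call(cbind, sigs)
      cons <- consensus_signatures(pool, min_cos = 0.8)
      # keep the r most stable clusters
      ord <- order(cons$sizes, decreasing = TRUE)
      keep <- ord[seq_len(min(r, length(ord)))]
      out[[as.character(r)]] <- list(
        signatures = cons$centres[, keep, drop = FALSE],
        mean_kl = mean(kls),
        stability = cons$sizes[keep] / n_bootstrap)
    }
    out
  })
}

# greedy cosine clustering of pooled bootstrap signatures
consensus_signatures <- function(pool, min_cos = 0.8) {
  centres <- NULL
  sizes <- integer(0)
  sums <- NULL
  for (j in seq_len(ncol(pool))) {
    v <- pool[, j]
    if (sum(v) == 0) next
    assigned <- FALSE
    if (!is.null(centres)) {
      sims <- apply(centres, 2, function(c0) cosine_sim(v, c0))
      best <- which.max(sims)
      if (sims[best] >= min_cos) {
        sums[, best] <- sums[, best] + v
        sizes[best] <- sizes[best] + 1L
        centres[, best] <- sums[, best] / sum(sums[, best])
        assigned <- TRUE
      }
    }
    if (!assigned) {
      sums <- cbind(sums, v)
      centres <- cbind(centres, v / sum(v))
      sizes <- c(sizes, 1L)
    }
  }
  colnames(centres) <- sprintf("consensus%d", seq_len(ncol(centres)))
  list(centres = centres, sizes = sizes)
}

#' Bootstrap cosine similarity between two profiles
#'
#' The observed cosine is compared against a label-swap null: the two
#' profiles' mutations are pooled and split at the observed totals, and the
#' cosine of the two resampled halves recomputed per bootstrap.  p is the
#' fraction of null cosines at least as large as the observed (with a +1/+1
#' pseudo-count).  Multinomial resampling of each profile gives the
#' bootstrap spread of the observed cosine itself.
#'
#' @param profile_a,profile_b \code{profile96} objects or 96-vectors.
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return list: \code{cosine}, \code{boot_cosines} (multinomial resampling),
#'   \code{null_cosines}, \code{p}.
#' @export
bootstrap_profile_similarity <- function(profile_a, profile_b,
                                         n_boot = 10000, seed = 1) {
  a <- as_profile_vector(profile_a); b <- as_profile_vector(profile_b)
  na <- sum(a); nb <- sum(b)
  if (na <= 0 || nb <= 0) stop("profiles must have positive totals")
  if (n_boot < 100) warning("n_boot < 100 gives a coarse p-value")
  obs <- cosine_sim(a, b)
  with_seed(seed, {
    boot_a <- rmultinom(n_boot, na, a / na)
    boot_b <- rmultinom(n_boot, nb, b / nb)
    boot_cos <- colSums(boot_a * boot_b) /
      (sqrt(colSums(boot_a^2)) * sqrt(colSums(boot_b^2)))
    pool <- a + b
    null_a <- rmultinom(n_boot, na, pool / sum(pool))
    null_b <- rmultinom(n_boot, nb, pool / sum(pool))
    null_cos <- colSums(null_a * null_b) /
      (sqrt(colSums(null_a^2)) * sqrt(colSums(null_b^2)))
    p <- (sum(null_cos >= obs) + 1) / (n_boot + 1)
    list(cosine = obs, boot_cosines = boot_cos, null_cosines = null_cos,
         p = p)
  })
}

#' Lineage-stratified 96-channel profiles
#'
#' Builds profiles for all mutations and for the stem, clade and private
#' strata; the three strata sum channel-wise to the full profile.
#'
#' @param mutations data.frame with \code{mutation_id}, \code{ref},
#'   \code{alt}, \code{context}.
#' @param lineage named character vector over the mutation ids.
#' @return named list of \code{profile96}: all, stem, clade, private.
#' @export
stratified_profiles <- function(mutations, lineage) {
  lin <- lineage[mutations$mutation_id]
  out <- list(all = build_profile96(mutations))
  for (lv in c("stem", "clade", "private"))
    out[[lv]] <- build_profile96(mutations[which(lin == lv), , drop = FALSE])
  out
}
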