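#' Cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression with a 0.01 pseudocount:
#' sqrt((GZMA + 0.01)(PRF1 + 0.01)).
#'
#' @param expression named numeric vector or single-sample list containing
#'   \code{GZMA} and \code{PRF1} TPM values, or a genes x samples matrix.
#' @param pseudocount additive pseudocount (default 0.01).
#' @return numeric score (vector over samples for matrix input).
#' @export
cytolytic_score <- function(expression, pseudocount = 0.01) {
  if (is.matrix(expression)) {
    if (!all(c("GZMA", "PRF1") %in% rownames(expression)))
      stop("expression must contain GZMA and PRF1")
    g <- expression["GZMA", ]; p <- expression["PRF1", ]
  } else {
    if (!all(c("GZMA", "PRF1") %in% names(expression)))
      stop("expression must contain GZMA and PRF1")
    g <- expression[["GZMA"]]; p <- expression[["PRF1"]]
  }
  if (any(g < 0) || any(p < 0)) stop("TPM values must be non-negative")
  sqrt((g + pseudocount) * (p + pseudocount))
}

#' Load the packaged synthetic immunophenogram panel
#'
#' A synthetic stand-in for the published 26-parameter immune panel (20
#' single factors plus 6 cell types over four categories: MHC, checkpoints
#' CP, effector cells EC, suppressor cells SC) with +1/-1 weights.  Users
#' may supply their own panel with the same columns.
#'
#' @return data.frame with columns \code{gene}, \code{parameter},
#'   \code{category}, \code{weight}.
#' @export
immune_panel <- function() {
  path <- system.file("extdata", "immune_panel_synthetic.csv",
                      package = "mima")
  panel <- read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

# gene universe the synthetic expression matrix must cover: the panel plus
# the CD3 complex and cytolytic genes
immune_genes <- function() {
  unique(c(immune_panel()$gene, "CD3D", "CD3G", "CD3E", "CD247",
           "GZMA", "PRF1"))
}

validate_panel <- function(panel) {
  stopifnot(all(c("gene", "parameter", "category", "weight") %in%
                  names(panel)))
  if (!all(panel$weight %in% c(-1, 1)))
    stop("panel weights must be +1 or -1")
  pc <- unique(panel[c("parameter", "category")])
  if (anyDuplicated(pc$parameter))
    stop("every parameter must map to exactly one category")
  pw <- unique(panel[c("parameter", "weight")])
  if (anyDuplicated(pw$parameter))
    stop("every parameter must carry one weight")
  invisible(panel)
}

#' Immunophenogram category scores and immunophenoscore (IPS)
#'
#' Gene expression is z-scored across samples; a parameter score is the
#' mean z of its member genes, a category score the mean of its member
#' parameters, and the aggregate the mean of the +1/-1 weighted parameter
#' scores.  IPS maps the aggregate linearly between the published anchors:
#' aggregate z <= 0 gives IPS 0 and aggregate z >= 3 gives IPS 10, with
#' interior values \code{round(z * 10 / 3)}.
#'
#' @param expression genes x samples numeric matrix (>= 3 samples).
#' @param panel panel data.frame (default the packaged synthetic panel).
#' @return list with \code{parameter_z} (parameters x samples),
#'   \code{category_scores}, \code{aggregate_z}, \code{ips} (integer 0-10
#'   per sample), \code{missing_genes}.
#' @export
immunophenogram <- function(expression, panel = immune_panel()) {
  validate_panel(panel)
  if (ncol(expression) < 3)
    stop("z-scores require at least 3 samples")
  present <- panel$gene %in% rownames(expression)
  missing_genes <- unique(panel$gene[!present])
  if (length(missing_genes))
    message(sprintf("%d panel genes absent from the matrix: %s",
                    length(missing_genes),
                    paste(head(missing_genes, 5), collapse = ", ")))
  panel <- panel[present, , drop = FALSE]
  if (!nrow(panel)) stop("no panel genes present in the expression matrix")
  expr <- expression[unique(panel$gene), , drop = FALSE]
  z <- t(scale(t(expr)))
  z[is.nan(z)] <- 0  # constant gene rows

  params <- unique(panel$parameter)
  parameter_z <- t(vapply(params, function(p) {
    genes <- panel$gene[panel$parameter == p]
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(expression))))
  weights <- panel$weight[match(params, panel$parameter)]
  cats <- panel$category[match(params, panel$parameter)]
  category_scores <- t(vapply(unique(cats), function(cc)
    colMeans(parameter_z[cats == cc, , drop = FALSE] *
               weights[cats == cc]),
    numeric(ncol(expression))))
  aggregate_z <- colMeans(parameter_z * weights)
  ips <- setNames(pmin(10L, pmax(0L, as.integer(round(aggregate_z * 10 / 3)))),
                  names(aggregate_z))
  list(parameter_z = parameter_z, category_scores = category_scores,
       aggregate_z = aggregate_z, ips = ips,
       missing_genes = missing_genes)
}

#' k-nearest-neighbour cell density
#'
#' For every point, density = N / (pi d_N^2) in pixel^-2, where d_N is the
#' Euclidean distance to the point's Nth nearest neighbour within the
#' density-defining population (\code{target_class}, self excluded).
#'
#' @param points data.frame with columns \code{x}, \code{y} and optionally
#'   \code{class}.
#' @param N neighbour order (default 50).
#' @param target_class optional class defining the density population; the
#'   density is still evaluated at every point.
#' @return numeric density per point (pixel^-2).
#' @export
knn_density <- function(points, N = 50, target_class = NULL) {
  stopifnot(all(c("x", "y") %in% names(points)))
  if (any(!is.finite(points$x)) || any(!is.finite(points$y)))
    stop("coordinates must be finite")
  pop <- if (is.null(target_class)) seq_len(nrow(points))
         else which(points$class == target_class)
  if (length(pop) < N + 1)
    stop(sprintf("density at order N = %d needs at least %d population points",
                 N, N + 1))
  px <- points$x[pop]; py <- points$y[pop]
  n <- nrow(points)
  dN <- numeric(n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    dx <- outer(points$x[idx], px, `-`)
    dy <- outer(points$y[idx], py, `-`)
    d2 <- dx * dx + dy * dy
    # exclude self-distance for points that belong to the population
    self <- match(idx, pop)
    has_self <- !is.na(self)
    if (any(has_self))
      d2[cbind(which(has_self), self[has_self])] <- Inf
    dN[idx] <- sqrt(apply(d2, 1, function(r) sort(r, partial = N)[N]))
  }
  N / (pi * dN^2)
}
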