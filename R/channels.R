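#' @importFrom stats aggregate cophenetic cor cor.test cutree dist hclust
#'   kmeans mad median p.adjust pbinom quantile rbeta rbinom rlnorm rmultinom
#'   rnbinom rnorm rpois runif sd setNames var wilcox.test
#' @importFrom utils head read.csv read.delim write.csv
NULL

DNA_BASES <- c("A", "C", "G", "T")

PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The fixed 96-channel substitution ordering
#'
#' Channels follow the canonical catalogue ordering: the six
#' pyrimidine-centred substitution classes (C>A, C>G, C>T, T>A, T>C, T>G),
#' each expanded over the 16 flanking-base contexts with the 5' base cycling
#' slowest (A, C, G, T) and the 3' base fastest, e.g. \code{A[C>A]A},
#' \code{A[C>A]C}, ..., \code{T[T>G]T}.
#'
#' @return Character vector of length 96 with labels such as \code{"A[C>A]A"}.
#' @export
channel_labels <- function() {
  labs <- character(0)
  for (sub in PYRIMIDINE_SUBS) {
    ref <- substr(sub, 1, 1)
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        labs <- c(labs, paste0(p5, "[", sub, "]", p3))
      }
    }
  }
  labs
}

CHANNELS <- local({
  labs <- character(96)
  i <- 0L
  for (sub in PYRIMIDINE_SUBS) for (p5 in DNA_BASES) for (p3 in DNA_BASES) {
    i <- i + 1L
    labs[i] <- paste0(p5, "[", sub, "]", p3)
  }
  labs
})

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement on plain character vectors (ACGT alphabet).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Map substitutions to pyrimidine-centred 96-channel labels
#'
#' Substitutions with a purine reference (A or G) are collapsed to the
#' pyrimidine representation by reverse-complementing ref, alt and the
#' trinucleotide context; the channel label is then
#' \code{5'[ref>alt]3'}.
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @param context reference-strand trinucleotide centred on the mutated base.
#' @return character vector of channel labels (NA where the context middle
#'   base does not equal ref, or ref == alt).
#' @export
channel_of <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  mid <- substr(context, 2, 2)
  bad <- mid != ref | ref == alt | nchar(context) != 3L
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp_base(ref), ref)
  a <- ifelse(purine, comp_base(alt), alt)
  p5 <- ifelse(purine, comp_base(substr(context, 3, 3)), substr(context, 1, 1))
  p3 <- ifelse(purine, comp_base(substr(context, 1, 1)), substr(context, 3, 3))
  out <- paste0(p5, "[", r, ">", a, "]", p3)
  out[bad] <- NA_character_
  out
}

#' Decode a channel label into its pyrimidine-strand parts
#'
#' @param channel character vector of labels like \code{"A[C>A]A"}.
#' @return data.frame with columns p5, ref, alt, p3, context.
#' @export
channel_parts <- function(channel) {
  data.frame(
    p5 = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    p3 = substr(channel, 7, 7),
    context = paste0(substr(channel, 1, 1), substr(channel, 3, 3),
                     substr(channel, 7, 7)),
    stringsAsFactors = FALSE
  )
}

# Collapse an arbitrary reference-strand 3-mer to its pyrimidine-centred
# representative ("+" if already pyrimidine-centred, "-" if reverse
# complemented).
pyr_context <- function(context) {
  mid <- substr(context, 2, 2)
  flip <- mid %in% c("A", "G")
  out <- context
  if (any(flip)) out[flip] <- revcomp(context[flip])
  list(context = out, strand = ifelse(flip, "-", "+"))
}
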