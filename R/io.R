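#' Write a case's per-sample mutations as VCF v4.2
#'
#' One VCF per sample with INFO keys GENE, EFFECT, TNC (trinucleotide
#' context) and FORMAT fields AD (ref,alt depths) and DP; only mutations
#' present in the sample are written.  Coordinates are gene-space
#' (CHROM = gene symbol, POS = position within the coding sequence).
#'
#' @param case a case element of a \code{\link{generate_cohort}} object.
#' @param dir output directory (created if needed).
#' @return invisible character vector of file paths.
#' @export
write_case_vcfs <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in case$sample_id) {
    present <- case$presence[, s]
    mut <- case$mutations[present, , drop = FALSE]
    dp <- case$depth[present, s]
    ad_alt <- case$alt_reads[present, s]
    path <- file.path(dir, paste0(s, ".vcf"))
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=mima_synthetic_cohort",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
      "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", s))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tGENE=%s;EFFECT=%s;TNC=%s\tAD:DP\t%d,%d:%d",
                    mut$chrom, mut$pos, mut$mutation_id, mut$ref, mut$alt,
                    mut$gene, mut$effect, mut$context,
                    dp - ad_alt, ad_alt, dp)
    writeLines(c(header, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a mutation table from a VCF written by \code{write_case_vcfs}
#'
#' @param path VCF file path.
#' @return data.frame with mutation, context and read-count columns.
#' @export
read_mutation_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    info <- fix$INFO
    grab <- function(k) sub(sprintf(".*%s=([^;]+).*", k), "\\1", info)
    gt <- v@gt[, 2]
    ad <- vapply(strsplit(sub(":.*", "", gt), ","), function(x)
      as.integer(x[2]), 0L)
    dp <- as.integer(sub(".*:", "", gt))
    return(data.frame(mutation_id = fix$ID, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, gene = grab("GENE"),
                      effect = grab("EFFECT"), context = grab("TNC"),
                      alt_reads = ad, depth = dp,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(info, k) sub(sprintf(".*%s=([^;]+).*", k), "\\1", info)
  data.frame(
    mutation_id = vapply(f, `[[`, "", 3),
    chrom = vapply(f, `[[`, "", 1),
    pos = as.integer(vapply(f, `[[`, "", 2)),
    ref = vapply(f, `[[`, "", 4),
    alt = vapply(f, `[[`, "", 5),
    gene = grab(vapply(f, `[[`, "", 8), "GENE"),
    effect = grab(vapply(f, `[[`, "", 8), "EFFECT"),
    context = grab(vapply(f, `[[`, "", 8), "TNC"),
    alt_reads = vapply(f, function(x)
      as.integer(strsplit(strsplit(x[10], ":")[[1]][1], ",")[[1]][2]), 0L),
    depth = vapply(f, function(x)
      as.integer(strsplit(x[10], ":")[[1]][2]), 0L),
    stringsAsFactors = FALSE)
}

#' Write AIRR-style clonotype tables
#'
#' Tab-separated with columns sample_id, chain, v_call, j_call, cdr3_nt,
#' cdr3_aa, duplicate_count.
#'
#' @param repertoires named list of clonotype data.frames.
#' @param path output TSV path.
#' @return invisible path.
#' @export
write_airr_tsv <- function(repertoires, path) {
  cols <- c("sample_id", "chain", "v_call", "j_call", "cdr3_nt", "cdr3_aa",
            "duplicate_count")
  df <- do.call(rbind, lapply(repertoires, function(x) x[cols]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read AIRR-style clonotype tables
#'
#' @param path TSV path.
#' @return named list of per-sample clonotype data.frames.
#' @export
read_airr_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  split(df, df$sample_id)
}

#' Write a signature catalog CSV
#'
#' Rows are the 96 channels (first column \code{channel} with labels like
#' \code{A[C>A]A}), remaining columns one signature each.
#'
#' @param catalog 96 x K matrix.
#' @param path CSV path.
#' @return invisible path.
#' @export
write_catalog_csv <- function(catalog, path) {
  df <- data.frame(channel = rownames(catalog), catalog,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signature catalog CSV
#'
#' @param path CSV path (first column channel labels).
#' @return 96 x K matrix in canonical channel order.
#' @export
read_catalog_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!setequal(rownames(m), CHANNELS))
    stop("catalog rows must be the 96 canonical channels")
  m[CHANNELS, , drop = FALSE]
}

#' Write per-case newick trees
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory.
#' @return invisible paths.
#' @export
write_case_trees <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$cases, function(cs) {
    p <- file.path(dir, paste0(cs$case_id, ".nwk"))
    ape::write.tree(cs$tree, file = p)
    p
  }, "")
  invisible(paths)
}

#' Write the cohort ground-truth manifest
#'
#' Serialises the manifest (seed, mixture, per-case lineage labels, true
#' exposures, TCR sharing labels, organ map, HLA LOH) as YAML or JSON by
#' file extension.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param path output path ending in .yaml/.yml or .json.
#' @return invisible path.
#' @export
write_manifest <- function(cohort, path) {
  m <- cohort$manifest
  m$cases <- lapply(m$cases, function(cs) {
    cs$lineage <- as.list(cs$lineage)
    cs$tcr_sharing <- lapply(cs$tcr_sharing, as.list)
    cs$organ <- as.list(cs$organ)
    cs$true_exposures <- apply(cs$true_exposures, 2, as.list,
                               simplify = FALSE)
    cs
  })
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(m, path)
  } else {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}
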