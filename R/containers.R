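#' Methylation count container
#'
#' Bundles per-CpG, per-sample methylated and total read counts with genomic
#' coordinates. CpGs are rows, samples are columns. A missing observation is
#' represented by `total = 0` (and `meth = 0`); this is also how masked
#' low-coverage observations are encoded by [filter_cpgs()].
#'
#' @param cpgs Data frame with columns `chrom` (character) and `pos`
#'   (1-based integer position), strictly increasing within chromosome.
#' @param meth,total Integer matrices (CpGs x samples) of methylated and
#'   total read counts, `0 <= meth <= total` everywhere.
#' @param samples Character vector of sample identifiers (column names).
#'
#' @return An object of class `meth_mat`.
#' @export
meth_matrix <- function(cpgs, meth, total, samples) {
  cpgs <- as_tibble(cpgs)
  stopifnot(all(c("chrom", "pos") %in% names(cpgs)))
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (!identical(dim(meth), dim(total))) {
    abort("`meth` and `total` must have identical dimensions.")
  }
  if (nrow(meth) != nrow(cpgs)) {
    abort("count matrices must have one row per CpG.")
  }
  if (ncol(meth) != length(samples)) {
    abort("count matrices must have one column per sample.")
  }
  if (anyNA(meth) || anyNA(total)) {
    abort("counts must not contain NA; encode missing observations as total = 0.")
  }
  if (any(meth < 0) || any(total < 0) || any(meth > total)) {
    abort("counts must satisfy 0 <= meth <= total.")
  }
  ord_ok <- !vapply(
    split(cpgs$pos, factor(cpgs$chrom, levels = unique(cpgs$chrom))),
    is.unsorted, logical(1), strictly = TRUE
  )
  if (!all(ord_ok)) {
    abort("CpG positions must be strictly increasing within each chromosome.")
  }
  dimnames(meth) <- dimnames(total) <- list(NULL, samples)
  structure(
    list(cpgs = cpgs, meth = meth, total = total, samples = as.character(samples)),
    class = "meth_mat"
  )
}

#' @export
print.meth_mat <- function(x, ...) {
  cat(
    "<meth_mat> ", nrow(x$cpgs), " CpGs x ", length(x$samples), " samples (",
    length(unique(x$cpgs$chrom)), " chromosomes)\n",
    sep = ""
  )
  cat(
    " covered cells:",
    sprintf("%.1f%%", 100 * mean(x$total > 0)),
    " mean depth:", sprintf("%.1f", mean(x$total[x$total > 0])), "\n"
  )
  invisible(x)
}

#' @export
dim.meth_mat <- function(x) dim(x$meth)

#' Subset a methylation matrix by CpG and/or sample
#'
#' @param x A `meth_mat`.
#' @param i CpG (row) index.
#' @param j Sample (column) index or sample names.
#' @param ... Unused.
#' @return A `meth_mat`.
#' @export
`[.meth_mat` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$cpgs))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  meth_matrix(
    x$cpgs[i, , drop = FALSE],
    x$meth[i, j, drop = FALSE],
    x$total[i, j, drop = FALSE],
    x$samples[j]
  )
}

#' Long-format view of a methylation matrix
#'
#' @param x A `meth_mat`.
#' @param ... Unused.
#' @return A tibble with one row per (CpG, sample) observation with
#'   `total > 0`, carrying `chrom`, `pos`, `sample_id`, `meth`, `total`,
#'   `ratio`.
#' @method as_tibble meth_mat
#' @export
as_tibble.meth_mat <- function(x, ...) {
  idx <- which(x$total > 0, arr.ind = TRUE)
  tibble(
    chrom = x$cpgs$chrom[idx[, 1]],
    pos = x$cpgs$pos[idx[, 1]],
    sample_id = x$samples[idx[, 2]],
    meth = x$meth[idx],
    total = x$total[idx],
    ratio = x$meth[idx] / x$total[idx]
  ) %>%
    arrange(.data$chrom, .data$pos, .data$sample_id)
}

#' Per-CpG methylation ratios
#'
#' @param x A `meth_mat`.
#' @return Numeric matrix of `meth / total` with `NA` where `total = 0`.
#' @export
meth_ratios <- function(x) {
  stopifnot(inherits(x, "meth_mat"))
  r <- x$meth / x$total
  r[x$total == 0] <- NA_real_
  r
}

#' Genotype dosage container
#'
#' Per-SNP alt-allele dosages (0/1/2, `NA` = missing) with read depths.
#' SNPs are rows, samples are columns.
#'
#' @param snps Data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, and logical `biallelic`.
#' @param dosage Numeric matrix of alt-allele dosages in `{0, 1, 2, NA}`.
#' @param depth Numeric matrix of per-call read depths.
#' @param samples Character vector of sample identifiers.
#' @return An object of class `geno_mat`.
#' @export
geno_matrix <- function(snps, dosage, depth, samples) {
  snps <- as_tibble(snps)
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(snps)))
  if (!"biallelic" %in% names(snps)) {
    snps$biallelic <- !grepl(",", snps$alt, fixed = TRUE)
  }
  dosage <- as.matrix(dosage)
  depth <- as.matrix(depth)
  if (!identical(dim(dosage), dim(depth)) || nrow(dosage) != nrow(snps) ||
      ncol(dosage) != length(samples)) {
    abort("dosage/depth must be SNP x sample matrices matching `snps` and `samples`.")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("dosages must be in {0, 1, 2} or NA.")
  }
  ord_ok <- !vapply(
    split(snps$pos, factor(snps$chrom, levels = unique(snps$chrom))),
    is.unsorted, logical(1)
  )
  if (!all(ord_ok)) abort("SNP positions must be sorted within chromosome.")
  dimnames(dosage) <- dimnames(depth) <- list(snps$id, samples)
  structure(
    list(snps = snps, dosage = dosage, depth = depth, samples = as.character(samples)),
    class = "geno_mat"
  )
}

#' @export
print.geno_mat <- function(x, ...) {
  cat(
    "<geno_mat> ", nrow(x$snps), " SNPs x ", length(x$samples), " samples; ",
    sum(x$snps$biallelic), " bi-allelic; call rate ",
    sprintf("%.1f%%", 100 * mean(!is.na(x$dosage))), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.geno_mat <- function(x) dim(x$dosage)

#' Genomic feature annotation set
#'
#' A named collection of interval tracks (1-based, closed intervals
#' internally; BED I/O converts from/to 0-based half-open). Recognised
#' track names: `cgi`, `genes`, `tss`, `tes`, `exons`, `first_exons`,
#' `introns`, `utr5`, `utr3`, `autoimmune`. Extra user tracks are allowed
#' and flow through annotation/enrichment unchanged.
#'
#' @param ... Named data frames, each with columns `chrom`, `start`, `end`
#'   (and optionally `strand`, `name`).
#' @return An object of class `feature_annotation`.
#' @export
feature_annotation <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1 && is.list(tracks[[1]]) && !is.data.frame(tracks[[1]])) {
    tracks <- tracks[[1]]
  }
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    abort("all annotation tracks must be named.")
  }
  tracks <- lapply(tracks, function(tr) {
    tr <- as_tibble(tr)
    stopifnot(all(c("chrom", "start", "end") %in% names(tr)))
    if (any(tr$start > tr$end)) abort("annotation intervals must satisfy start <= end.")
    arrange(tr, .data$chrom, .data$start, .data$end)
  })
  structure(tracks, class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat("<feature_annotation> tracks:\n")
  for (nm in names(x)) cat("  ", nm, ": ", nrow(x[[nm]]), " intervals\n", sep = "")
  invisible(x)
}

# internal: tibble of intervals -> GRanges (1-based closed)
.track_granges <- function(tr) {
  strand <- if ("strand" %in% names(tr)) tr$strand else "*"
  GenomicRanges::GRanges(
    seqnames = tr$chrom,
    ranges = IRanges::IRanges(start = tr$start, end = tr$end),
    strand = strand
  )
}

.cpg_granges <- function(cpgs) {
  GenomicRanges::GRanges(
    seqnames = cpgs$chrom,
    ranges = IRanges::IRanges(start = cpgs$pos, width = 1)
  )
}
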