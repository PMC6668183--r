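#' Apply the CpG inclusion rules used before association testing
#'
#' Rules, in order: (1) drop sex-chromosome CpGs (chrX/chrY); (2) mask
#' (set to missing, i.e. `total = 0`) any observation with depth below
#' `min_depth` -- below-threshold observations are considered unreliable
#' and are hidden from all downstream models, not only from the
#' sample-count rule; (3) drop CpGs observed in fewer than `min_samples`
#' unmasked samples; (4) drop non-variable CpGs (standard deviation of
#' the per-sample methylation ratio over unmasked samples equal to 0; a
#' CpG with fewer than 2 unmasked samples has no defined variance and is
#' dropped here too).
#'
#' @param m A [meth_matrix()].
#' @param min_depth Minimum read depth for an observation to count
#'   (default 15).
#' @param min_samples Minimum number of unmasked samples per CpG
#'   (default 30).
#' @return A list with `methylation` (the filtered [meth_matrix()]) and
#'   `report` (a `filter_report` tibble of per-rule removal counts).
#' @export
filter_cpgs <- function(m, min_depth = 15, min_samples = 30) {
  stopifnot(inherits(m, "meth_mat"))
  if (nrow(m$cpgs) == 0) abort("methylation matrix is empty.")
  if (min_samples > length(m$samples)) {
    abort(sprintf("min_samples (%d) exceeds cohort size (%d).",
                  min_samples, length(m$samples)))
  }
  n_in <- nrow(m$cpgs)

  sex <- m$cpgs$chrom %in% c("chrX", "chrY", "X", "Y")
  n_sex <- sum(sex)
  m <- m[!sex, ]

  mask <- m$total < min_depth
  n_masked_obs <- sum(mask & m$total > 0)
  m$total[mask] <- 0L
  m$meth[mask] <- 0L

  n_obs <- rowSums(m$total > 0)
  low <- n_obs < min_samples
  n_low <- sum(low)
  m <- m[!low, ]

  r <- meth_ratios(m)
  sds <- apply(r, 1, sd, na.rm = TRUE)
  nonvar <- is.na(sds) | sds == 0
  n_nonvar <- sum(nonvar)
  m <- m[!nonvar, ]

  report <- structure(
    tibble(
      rule = c("sex-chromosome", "low-sample-coverage", "non-variable"),
      removed = c(n_sex, n_low, n_nonvar)
    ),
    class = c("filter_report", "tbl_df", "tbl", "data.frame"),
    n_input = n_in, n_surviving = nrow(m$cpgs),
    n_masked_observations = n_masked_obs,
    unit = "CpG"
  )
  list(methylation = m, report = report)
}

#' Apply the SNP inclusion rules used before meQTL mapping
#'
#' Genotype calls with read depth below `min_depth` are set missing;
#' non-bi-allelic SNPs are dropped; SNPs whose post-masking call rate is
#' not above `min_call_rate` are dropped.
#'
#' @param g A [geno_matrix()].
#' @param min_depth Minimum read depth per genotype call (default 10).
#' @param min_call_rate Required fraction of subjects with calls,
#'   exclusive bound (default 0.7, i.e. "more than 70%").
#' @return A list with `genotypes` (filtered [geno_matrix()]) and
#'   `report` (a `filter_report` tibble).
#' @export
filter_snps <- function(g, min_depth = 10, min_call_rate = 0.7) {
  stopifnot(inherits(g, "geno_mat"))
  if (nrow(g$snps) == 0) abort("genotype matrix is empty.")
  n_in <- nrow(g$snps)

  multi <- !g$snps$biallelic
  n_multi <- sum(multi)
  g <- .subset_geno(g, !multi)

  mask <- g$depth < min_depth
  n_masked_obs <- sum(mask & !is.na(g$dosage))
  g$dosage[mask] <- NA_real_

  call_rate <- rowMeans(!is.na(g$dosage))
  low <- !(call_rate > min_call_rate)
  n_low <- sum(low)
  g <- .subset_geno(g, !low)

  report <- structure(
    tibble(
      rule = c("non-biallelic", "low-call-rate"),
      removed = c(n_multi, n_low)
    ),
    class = c("filter_report", "tbl_df", "tbl", "data.frame"),
    n_input = n_in, n_surviving = nrow(g$snps),
    n_masked_observations = n_masked_obs,
    unit = "SNP"
  )
  list(genotypes = g, report = report)
}

.subset_geno <- function(g, keep) {
  structure(
    list(
      snps = g$snps[keep, , drop = FALSE],
      dosage = g$dosage[keep, , drop = FALSE],
      depth = g$depth[keep, , drop = FALSE],
      samples = g$samples
    ),
    class = "geno_mat"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", attr(x, "unit"), "s: ", attr(x, "n_input"),
      " in, ", attr(x, "n_surviving"), " surviving (",
      attr(x, "n_masked_observations"), " observations masked)\n", sep = "")
  print(tibble(rule = x$rule, removed = x$removed))
  invisible(x)
}
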