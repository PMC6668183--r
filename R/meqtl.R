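#' Map cis-meQTLs by per-pair least squares
#'
#' Reproduces the MatrixEQTL-style additive linear scan: for every
#' SNP-CpG pair within `window` bp, the per-sample methylation ratio is
#' regressed on alt-allele dosage by ordinary least squares (no
#' covariates), giving a t-statistic with `n - 2` degrees of freedom.
#' CpG selection, applied internally: call rate above `min_call_frac` of
#' the cohort and methylation-ratio variance in the top
#' `var_top_frac` of the candidate CpGs. Benjamini-Hochberg q-values
#' are computed over all tests and a genome-wide-significant subset is
#' flagged at `p < gw_p`.
#'
#' @param m A filtered [meth_matrix()].
#' @param g A filtered [geno_matrix()] (bi-allelic, depth-masked; see
#'   [filter_snps()]).
#' @param window Maximum SNP-CpG distance in bp (default 250000, i.e. a
#'   500-kb window centred on the CpG).
#' @param min_call_frac CpG call-rate bound, exclusive (default 0.5).
#' @param var_top_frac Fraction of most-variable CpGs retained
#'   (default 0.5).
#' @param gw_p Genome-wide significance threshold (default 5e-8).
#' @return A `meqtl_result` tibble: `snp_id`, `snp_chrom`, `snp_pos`,
#'   `cpg_chrom`, `cpg_pos`, `slope` (methylation-ratio change per alt
#'   allele), `t_stat`, `p_value`, `q_value`, `n`, `gw_significant`.
#'   Attributes `n_pairs_tested` and `n_pairs_skipped` (constant dosage
#'   or methylation, or n < 3).
#' @export
map_cis_meqtls <- function(m, g, window = 250000, min_call_frac = 0.5,
                           var_top_frac = 0.5, gw_p = 5e-8) {
  stopifnot(inherits(m, "meth_mat"), inherits(g, "geno_mat"))
  common <- intersect(m$samples, g$samples)
  if (length(common) < 3) abort("fewer than 3 samples shared between matrices.")
  mi <- match(common, m$samples)
  gi <- match(common, g$samples)
  n_cohort <- length(common)

  ratios <- meth_ratios(m)[, mi, drop = FALSE]
  call_rate <- rowMeans(!is.na(ratios))
  vars <- apply(ratios, 1, var, na.rm = TRUE)
  cand <- call_rate > min_call_frac & !is.na(vars)
  var_cut <- quantile(vars[cand], 1 - var_top_frac, na.rm = TRUE, names = FALSE)
  keep_cpg <- cand & vars >= var_cut
  cpg_tab <- m$cpgs[keep_cpg, , drop = FALSE]
  Y <- ratios[keep_cpg, , drop = FALSE]

  dosage <- g$dosage[, gi, drop = FALSE]
  out <- list()
  n_skipped <- 0L
  for (si in seq_len(nrow(g$snps))) {
    ch <- g$snps$chrom[si]
    sp <- g$snps$pos[si]
    rows <- which(cpg_tab$chrom == ch & abs(cpg_tab$pos - sp) <= window)
    if (!length(rows)) next
    gv <- dosage[si, ]
    g_ok <- !is.na(gv)
    if (sum(g_ok) < 3 || length(unique(gv[g_ok])) < 2) {
      n_skipped <- n_skipped + length(rows)
      next
    }
    Yb <- Y[rows, , drop = FALSE]
    M <- !is.na(Yb)
    M[, !g_ok] <- FALSE
    Y0 <- Yb
    Y0[!M] <- 0
    gv0 <- ifelse(g_ok, gv, 0)
    nn <- rowSums(M)
    Sx <- as.numeric(M %*% gv0)
    Sxx <- as.numeric(M %*% (gv0^2))
    Sy <- rowSums(Y0)
    Syy <- rowSums(Y0^2)
    Sxy <- as.numeric(Y0 %*% gv0)
    ssx <- Sxx - Sx^2 / nn
    ssy <- Syy - Sy^2 / nn
    valid <- nn >= 3 & ssx > 1e-12 & ssy > 1e-12
    n_skipped <- n_skipped + sum(!valid)
    if (!any(valid)) next
    slope <- (Sxy - Sx * Sy / nn) / ssx
    rss <- pmax(ssy - slope^2 * ssx, 0)
    se <- sqrt(rss / (nn - 2) / ssx)
    tstat <- slope / se
    pval <- 2 * pt(-abs(tstat), df = nn - 2)
    out[[length(out) + 1L]] <- tibble(
      snp_id = g$snps$id[si], snp_chrom = ch, snp_pos = sp,
      cpg_chrom = cpg_tab$chrom[rows], cpg_pos = cpg_tab$pos[rows],
      slope = slope, t_stat = tstat, p_value = pval, n = nn
    )[valid, ]
  }
  res <- if (length(out)) bind_rows(out) else tibble(
    snp_id = character(), snp_chrom = character(), snp_pos = integer(),
    cpg_chrom = character(), cpg_pos = integer(), slope = numeric(),
    t_stat = numeric(), p_value = numeric(), n = integer()
  )
  res$q_value <- if (nrow(res)) p.adjust(res$p_value, method = "BH") else numeric(0)
  res$gw_significant <- res$p_value < gw_p
  structure(
    res,
    class = c("meqtl_result", class(res)),
    n_pairs_tested = nrow(res), n_pairs_skipped = n_skipped,
    n_cpgs_selected = nrow(cpg_tab), n_cohort = n_cohort, window = window
  )
}

#' Genotype-adjusted refits and gDMR/ngDMR classification
#'
#' For each differentially methylated CpG with at least one significant
#' cis-meQTL (`q_value < meqtl_q`), the lead meQTL (smallest meQTL p;
#' ties broken by smaller SNP-CpG distance, then lower SNP position)
#' dosage is appended to the original binomial regression model and the
#' CpG refitted on the samples with a genotype call. If more than
#' `max_missing` of the samples lack the lead dosage the next-best
#' significant meQTL is used; with none available the CpG is kept
#' unadjusted. A refitted CpG "remains significant" when its
#' Bonferroni-adjusted p-value (raw refit p multiplied by the number of
#' refitted CpGs, capped at 1) is below `alpha`.
#'
#' DMR labels: `ngDMR` when the members still satisfy the DMR
#' membership criteria after adjustment (a run of at least `min_cpgs`
#' consecutive surviving members with the original direction), `gDMR`
#' when testable but no longer satisfying them, `untestable` when no
#' member CpG has a significant meQTL in the window. A member without a
#' usable meQTL stays unadjusted and survives on its original nominal
#' p-value (`< p_threshold`).
#'
#' @param dmcs Tibble of significant CpGs (rows of an `ewas_result`
#'   whose `q_value` beat the study threshold).
#' @param dmrs A `dmr_result` from [call_dmrs()].
#' @param meqtls A `meqtl_result` from [map_cis_meqtls()].
#' @param m,s,g Methylation matrix, sample sheet and genotype matrix.
#' @param model The original [model_spec()] (or its name).
#' @param meqtl_q Significance threshold defining usable meQTLs
#'   (default 0.01).
#' @param alpha Threshold on the Bonferroni-adjusted refit p
#'   (default 0.01).
#' @param p_threshold Nominal membership threshold for unadjusted
#'   members (default 0.01).
#' @param min_cpgs Minimum surviving run length for `ngDMR` (default 3).
#' @param rule `"criteria"` (default) or `"any"` (any member remaining
#'   significant makes the DMR `ngDMR`).
#' @param max_missing Maximum tolerated fraction of samples without a
#'   lead-SNP call (default 0.3).
#' @return A `genetic_classification` tibble, one row per DMR: `dmr_id`,
#'   `chrom`, `start`, `end`, `n_members`, `n_testable`, `n_remaining`,
#'   `label`. Per-CpG refits are attached as attribute `dmc_refits`
#'   (accessor [dmc_refits()]).
#' @export
adjust_and_classify <- function(dmcs, dmrs, meqtls, m, s, g, model,
                                meqtl_q = 0.01, alpha = 0.01,
                                p_threshold = 0.01, min_cpgs = 3,
                                rule = c("criteria", "any"),
                                max_missing = 0.3) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "meth_mat"), inherits(g, "geno_mat"))
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  dmcs <- as_tibble(dmcs)

  sig_meqtls <- as_tibble(meqtls) %>%
    filter(!is.na(.data$q_value), .data$q_value < meqtl_q) %>%
    mutate(dist = abs(.data$snp_pos - .data$cpg_pos)) %>%
    arrange(.data$p_value, .data$dist, .data$snp_pos)
  meqtl_key <- paste(sig_meqtls$cpg_chrom, sig_meqtls$cpg_pos)

  d <- .build_design(s, spec)
  col_m <- match(d$samples$sample_id, m$samples)
  col_g <- match(d$samples$sample_id, g$samples)
  X <- d$X
  key_m <- paste(m$cpgs$chrom, m$cpgs$pos)

  refit_one <- function(ch, pos) {
    rec <- list(lead_snp = NA_character_, beta_adj = NA_real_,
                p_raw = NA_real_, n_refit = NA_integer_, refitted = FALSE,
                dir_adj = NA_real_)
    leads <- sig_meqtls[meqtl_key == paste(ch, pos), , drop = FALSE]
    row_m <- match(paste(ch, pos), key_m)
    if (!nrow(leads) || is.na(row_m)) return(rec)
    for (l in seq_len(nrow(leads))) {
      srow <- match(leads$snp_id[l], g$snps$id)
      if (is.na(srow)) next
      gv <- g$dosage[srow, col_g]
      if (mean(is.na(gv)) > max_missing) next
      ok <- !is.na(gv)
      Xg <- cbind(X[ok, , drop = FALSE], dosage = gv[ok])
      fit <- .fit_one(Xg, m$meth[row_m, col_m][ok], m$total[row_m, col_m][ok])
      if (!fit$converged) next
      rec$lead_snp <- leads$snp_id[l]
      rec$beta_adj <- fit$beta
      rec$p_raw <- fit$p
      rec$n_refit <- fit$n_used
      rec$refitted <- TRUE
      rec$dir_adj <- sign(fit$beta)
      return(rec)
    }
    rec
  }

  refs <- purrr::map2(dmcs$chrom, dmcs$pos, refit_one)
  refits <- tibble(
    chrom = dmcs$chrom, pos = dmcs$pos,
    p_orig = dmcs$p_value %||% NA_real_,
    direction_orig = if ("beta" %in% names(dmcs)) sign(dmcs$beta) else NA_real_,
    lead_snp = purrr::map_chr(refs, "lead_snp"),
    beta_adj = purrr::map_dbl(refs, "beta_adj"),
    p_adj_raw = purrr::map_dbl(refs, "p_raw"),
    direction_adj = purrr::map_dbl(refs, "dir_adj"),
    n_refit = purrr::map_int(refs, ~ as.integer(.x$n_refit)),
    refitted = purrr::map_lgl(refs, "refitted")
  )
  n_refitted <- sum(refits$refitted)
  refits$p_bonferroni <- ifelse(
    refits$refitted, pmin(refits$p_adj_raw * max(n_refitted, 1), 1), NA_real_
  )
  refits$remains_significant <- refits$refitted & refits$p_bonferroni < alpha

  # classify each DMR against the refitted members
  dmc_key <- paste(refits$chrom, refits$pos)
  labels <- character(nrow(dmrs))
  n_testable <- n_remaining <- integer(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    mem_pos <- dmrs$members[[i]]
    mk <- paste(dmrs$chrom[i], mem_pos)
    rows <- match(mk, dmc_key)
    dir_num <- if (dmrs$direction[i] == "hyper") 1 else -1
    has_meqtl <- !is.na(rows) & refits$refitted[rows]
    n_testable[i] <- sum(has_meqtl, na.rm = TRUE)
    if (n_testable[i] == 0) {
      labels[i] <- "untestable"
      n_remaining[i] <- 0L
      next
    }
    survives <- logical(length(mem_pos))
    for (j in seq_along(mem_pos)) {
      rj <- rows[j]
      if (!is.na(rj) && refits$refitted[rj]) {
        survives[j] <- refits$remains_significant[rj] &&
          !is.na(refits$direction_adj[rj]) &&
          refits$direction_adj[rj] == dir_num
      } else {
        # no usable meQTL: the member stays unadjusted and keeps its
        # original (DMR-qualifying) nominal significance
        survives[j] <- TRUE
      }
    }
    n_remaining[i] <- sum(survives & has_meqtl) +
      sum(survives & !has_meqtl)
    ok <- if (rule == "any") {
      any(survives[has_meqtl])
    } else {
      r <- rle(survives)
      any(r$values & r$lengths >= min_cpgs)
    }
    labels[i] <- if (ok) "ngDMR" else "gDMR"
  }
  out <- tibble(
    dmr_id = sprintf("DMR_%03d", seq_len(nrow(dmrs))),
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    n_members = dmrs$n_cpgs, n_testable = n_testable,
    n_remaining = n_remaining, label = labels
  )
  structure(
    out,
    class = c("genetic_classification", class(out)),
    dmc_refits = refits, n_refitted = n_refitted,
    alpha = alpha, rule = rule
  )
}

#' Per-CpG genotype-adjusted refit table
#'
#' @param x A `genetic_classification` from [adjust_and_classify()].
#' @return The tibble of per-DMC refits (lead SNP, adjusted beta, raw
#'   and Bonferroni-adjusted p, survival flag).
#' @export
dmc_refits <- function(x) {
  stopifnot(inherits(x, "genetic_classification"))
  attr(x, "dmc_refits")
}
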