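#' Annotate CpGs with genomic feature flags
#'
#' Each CpG receives independent logical flags per track plus a mutually
#' exclusive CpG-island class derived from the distance to the nearest
#' CGI edge: inside a CGI -> `cgi`; 1-2000 bp outside -> `cgi_shore`;
#' 2001-4000 bp -> `cgi_shelf`; farther -> `open_sea`. Promoter windows
#' (`tss1500`) extend 1500 bp on both sides of a transcription start
#' site, and transcription-end windows (`tes1500`) likewise; a CpG is
#' `intergenic` iff it lies in no gene-model interval and in no
#' TSS1500/TES window.
#'
#' @param cpgs Data frame with `chrom` and `pos` columns.
#' @param ann A [feature_annotation()].
#' @param promoter_bp Promoter (and TES) window half-width (default
#'   1500).
#' @param shore_bp,shelf_bp Shore and shelf widths in bp (defaults 2000
#'   each).
#' @return A `feature_classification` tibble: `chrom`, `pos`, one
#'   logical column per feature (`tss1500`, `utr5`, `first_exon`,
#'   `exon`, `intron`, `utr3`, `tes1500`, `cgi`, `cgi_shore`,
#'   `cgi_shelf`, `open_sea`, `gene_body`, `intergenic`, `autoimmune`,
#'   plus any extra tracks), and `cgi_class`. CpGs on chromosomes absent
#'   from a track get `FALSE` there; the count of such CpGs for the CGI
#'   track is reported as attribute `n_unannotated`.
#' @export
annotate_features <- function(cpgs, ann, promoter_bp = 1500,
                              shore_bp = 2000, shelf_bp = 2000) {
  stopifnot(inherits(ann, "feature_annotation"))
  cpgs <- as_tibble(cpgs)[, c("chrom", "pos")]
  gr <- .cpg_granges(cpgs)
  in_track <- function(track_gr) {
    # seqlevel mismatches are expected (a CpG may sit on a chromosome a
    # track does not cover) and handled by the all-false convention
    suppressWarnings(IRanges::overlapsAny(gr, track_gr, ignore.strand = TRUE))
  }
  flags <- tibble(chrom = cpgs$chrom, pos = cpgs$pos)

  point_window <- function(tr, half) {
    tr$start <- pmax(1, tr$start - half)
    tr$end <- tr$end + half
    tr
  }
  if ("tss" %in% names(ann)) {
    flags$tss1500 <- in_track(.track_granges(point_window(ann$tss, promoter_bp)))
  }
  if ("utr5" %in% names(ann)) flags$utr5 <- in_track(.track_granges(ann$utr5))
  if ("first_exons" %in% names(ann)) {
    flags$first_exon <- in_track(.track_granges(ann$first_exons))
  }
  if ("exons" %in% names(ann)) flags$exon <- in_track(.track_granges(ann$exons))
  if ("introns" %in% names(ann)) flags$intron <- in_track(.track_granges(ann$introns))
  if ("utr3" %in% names(ann)) flags$utr3 <- in_track(.track_granges(ann$utr3))
  if ("tes" %in% names(ann)) {
    flags$tes1500 <- in_track(.track_granges(point_window(ann$tes, promoter_bp)))
  }
  if ("autoimmune" %in% names(ann)) {
    flags$autoimmune <- in_track(.track_granges(ann$autoimmune))
  }
  extra <- setdiff(
    names(ann),
    c("cgi", "genes", "tss", "tes", "exons", "first_exons", "introns",
      "utr5", "utr3", "autoimmune")
  )
  for (nm in extra) flags[[nm]] <- in_track(.track_granges(ann[[nm]]))

  # CGI class by distance to the nearest island edge
  n_unannotated <- 0L
  if ("cgi" %in% names(ann)) {
    cg_red <- as_tibble(as.data.frame(
      GenomicRanges::reduce(.track_granges(ann$cgi))
    )) %>%
      rename(chrom = "seqnames") %>%
      mutate(chrom = as.character(.data$chrom)) %>%
      arrange(.data$chrom, .data$start)
    dist <- rep(Inf, nrow(cpgs))
    for (ch in unique(cpgs$chrom)) {
      ci <- which(cpgs$chrom == ch)
      tr <- cg_red[cg_red$chrom == ch, ]
      if (!nrow(tr)) {
        n_unannotated <- n_unannotated + length(ci)
        next
      }
      p <- cpgs$pos[ci]
      j <- findInterval(p, tr$start)
      d_left <- ifelse(j >= 1,
                       pmax(p - tr$end[pmax(j, 1)], 0),
                       Inf)
      d_right <- ifelse(j < nrow(tr), tr$start[pmin(j + 1L, nrow(tr))] - p, Inf)
      dist[ci] <- pmin(d_left, d_right)
    }
    flags$cgi <- dist == 0
    flags$cgi_shore <- dist > 0 & dist <= shore_bp
    flags$cgi_shelf <- dist > shore_bp & dist <= shore_bp + shelf_bp
    flags$open_sea <- dist > shore_bp + shelf_bp
    flags$cgi_class <- case_when(
      flags$cgi ~ "cgi",
      flags$cgi_shore ~ "shore",
      flags$cgi_shelf ~ "shelf",
      TRUE ~ "open_sea"
    )
  }
  if ("genes" %in% names(ann)) {
    flags$gene_body <- in_track(.track_granges(ann$genes))
    flags$intergenic <- !flags$gene_body &
      !(flags[["tss1500"]] %||% FALSE) & !(flags[["tes1500"]] %||% FALSE)
  }
  if (n_unannotated > 0) {
    warn(sprintf("%d CpGs lie on chromosomes absent from the CGI track.",
                 n_unannotated))
  }
  structure(flags, class = c("feature_classification", class(flags)),
            n_unannotated = n_unannotated)
}

#' Fisher enrichment of DMR CpGs across genomic features
#'
#' One two-sided Fisher's exact test per feature on the 2x2 table of
#' (in feature vs not) x (DMR CpG vs other background CpG); the
#' background set must contain the DMR CpGs ("all testable CpGs"). Fold
#' change is `(k/n) / (K/N)`; values below 1 denote depletion. No
#' multiplicity correction is applied across features.
#'
#' @param dmr_cpgs,background_cpgs Data frames with `chrom`, `pos`;
#'   `dmr_cpgs` must be a subset of `background_cpgs`.
#' @param ann A [feature_annotation()].
#' @param features Optional character vector restricting the features
#'   tested (default: every flag produced by [annotate_features()]).
#' @return An `enrichment_result` tibble: `feature`, `k` (DMR CpGs in
#'   feature), `n` (DMR CpGs), `K` (background CpGs in feature), `N`
#'   (background CpGs), `fold_change`, `p_value`. An empty feature
#'   (`K = 0`) reports `fold_change = NA`, `p_value = 1`.
#' @export
feature_enrichment <- function(dmr_cpgs, background_cpgs, ann,
                               features = NULL) {
  dmr_cpgs <- as_tibble(dmr_cpgs)
  background_cpgs <- as_tibble(background_cpgs)
  if (nrow(dmr_cpgs) == 0) abort("the DMR CpG set is empty.")
  key_d <- paste(dmr_cpgs$chrom, dmr_cpgs$pos)
  key_b <- paste(background_cpgs$chrom, background_cpgs$pos)
  if (!all(key_d %in% key_b)) {
    abort("dmr_cpgs must be a subset of background_cpgs.")
  }
  fc <- suppressWarnings(annotate_features(background_cpgs, ann))
  flag_cols <- names(fc)[vapply(fc, is.logical, logical(1))]
  if (!is.null(features)) flag_cols <- intersect(flag_cols, features)
  in_dmr <- key_b %in% key_d
  N <- nrow(background_cpgs)
  n <- sum(in_dmr)
  rows <- lapply(flag_cols, function(f) {
    feat <- fc[[f]]
    K <- sum(feat)
    k <- sum(feat & in_dmr)
    if (K == 0) {
      return(tibble(feature = f, k = k, n = n, K = K, N = N,
                    fold_change = NA_real_, p_value = 1))
    }
    tab <- matrix(c(k, n - k, K - k, (N - K) - (n - k)), 2, 2)
    tibble(
      feature = f, k = k, n = n, K = K, N = N,
      fold_change = (k / n) / (K / N),
      p_value = fisher.test(tab)$p.value
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Discovery-to-validation replication of DMCs
#'
#' Both result sets are restricted to their common tested CpGs. A
#' discovery DMC (`q_value < disc_q`) is "replicated" when its
#' validation p-value is below `val_p` with the same direction of
#' change. The fold enrichment compares the observed overlap of the
#' discovery DMC set with the validation DMC set (`p < val_p`,
#' direction-free) to its expectation under independence
#' (`n_discovery * n_validation / n_common`), with a hypergeometric
#' upper-tail p-value.
#'
#' @param discovery,validation `ewas_result` tibbles keyed by
#'   (`chrom`, `pos`).
#' @param val_p Validation nominal threshold (default 0.05).
#' @param disc_q Discovery significance threshold (default 0.01).
#' @return A one-row `replication_result` tibble: `n_common_tested`,
#'   `n_discovery_dmcs_tested`, `n_validation_dmcs`, `n_overlap`,
#'   `n_replicated`, `replication_rate`, `fold_enrichment`, `p_value`.
#' @export
replicate_ewas <- function(discovery, validation, val_p = 0.05,
                           disc_q = 0.01) {
  discovery <- as_tibble(discovery)
  validation <- as_tibble(validation)
  if ("converged" %in% names(discovery)) {
    discovery <- filter(discovery, .data$converged)
  }
  if ("converged" %in% names(validation)) {
    validation <- filter(validation, .data$converged)
  }
  dd <- select(discovery, "chrom", "pos", disc_p = "p_value",
               disc_q = "q_value", disc_dir = "direction")
  vv <- select(validation, "chrom", "pos", val_p_value = "p_value",
               val_dir = "direction")
  common <- dplyr::inner_join(dd, vv, by = c("chrom", "pos"))
  if (nrow(common) == 0) abort("no common tested CpGs between the cohorts.")

  n_common <- nrow(common)
  disc_dmc <- !is.na(common$disc_q) & common$disc_q < disc_q
  val_dmc <- !is.na(common$val_p_value) & common$val_p_value < val_p
  n_disc <- sum(disc_dmc)
  n_val <- sum(val_dmc)
  n_overlap <- sum(disc_dmc & val_dmc)
  n_replicated <- sum(disc_dmc & val_dmc &
                        common$disc_dir == common$val_dir)
  expected <- n_disc * n_val / n_common
  fold <- if (n_disc == 0 || n_val == 0) NA_real_ else n_overlap / expected
  pval <- if (n_disc == 0 || n_val == 0) {
    1
  } else {
    phyper(n_overlap - 1, n_disc, n_common - n_disc, n_val, lower.tail = FALSE)
  }
  out <- tibble(
    n_common_tested = n_common,
    n_discovery_dmcs_tested = n_disc,
    n_validation_dmcs = n_val,
    n_overlap = n_overlap,
    n_replicated = n_replicated,
    replication_rate = if (n_disc == 0) 0 else n_replicated / n_disc,
    fold_enrichment = fold,
    p_value = pval
  )
  class(out) <- c("replication_result", class(out))
  out
}

#' Discovery-to-validation replication of DMRs
#'
#' A discovery DMR replicates when at least one validation-cohort CpG
#' inside the region has nominal `p < val_p` with the same direction of
#' change.
#'
#' @param dmrs A `dmr_result` from [call_dmrs()].
#' @param validation An `ewas_result` for the validation cohort.
#' @param val_p Nominal threshold (default 0.05).
#' @return The `dmrs` tibble with columns `n_validation_cpgs` and
#'   `replicated`; attribute `replication_rate`.
#' @export
replicate_dmrs <- function(dmrs, validation, val_p = 0.05) {
  validation <- as_tibble(validation)
  if ("converged" %in% names(validation)) {
    validation <- filter(validation, .data$converged)
  }
  n_val <- integer(nrow(dmrs))
  rep_ok <- logical(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    v <- validation[validation$chrom == dmrs$chrom[i] &
                      validation$pos >= dmrs$start[i] &
                      validation$pos <= dmrs$end[i], ]
    n_val[i] <- nrow(v)
    dir_num <- if (dmrs$direction[i] == "hyper") 1 else -1
    rep_ok[i] <- any(v$p_value < val_p & v$direction == dir_num, na.rm = TRUE)
  }
  dmrs$n_validation_cpgs <- n_val
  dmrs$replicated <- rep_ok
  tested <- n_val > 0
  attr(dmrs, "replication_rate") <-
    if (any(tested)) mean(rep_ok[tested]) else NA_real_
  attr(dmrs, "n_tested") <- sum(tested)
  dmrs
}
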