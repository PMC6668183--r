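#' Call differentially methylated regions (seed-and-merge)
#'
#' Algorithm: (1) seed CpGs are those with `q < q_threshold`; (2)
#' candidate regions are the per-chromosome union of closed windows
#' `[seed - window, seed + window]`, overlapping windows merged; (3)
#' within each candidate region, tested CpGs are scanned in position
#' order and maximal runs extracted in which every CpG has nominal
#' `p < p_threshold` and the same direction of change (a CpG failing
#' either condition breaks the run); (4) runs with at least `min_cpgs`
#' members containing at least one seed are emitted. "Consecutive"
#' means adjacent in the ordered list of tested CpGs: CpGs that were
#' filtered out before testing cannot break a run.
#'
#' @param results An `ewas_result` tibble (or any tibble with `chrom`,
#'   `pos`, `p_value`, `q_value`, `beta` and optionally `methdiff`,
#'   `converged`), sorted by position within chromosome.
#' @param q_threshold Seed significance threshold (default 0.01).
#' @param p_threshold Nominal membership threshold (default 0.01).
#' @param window Candidate half-window in bp around each seed (default
#'   200; boundaries closed, so a CpG exactly at `seed +/- window` is
#'   inside).
#' @param min_cpgs Minimum member count (default 3).
#' @param annotation Optional [feature_annotation()] with a `tss` track;
#'   when supplied, each DMR is annotated with its nearest TSS distance
#'   and gene label.
#' @return A `dmr_result` tibble: `chrom`, `start`, `end` (positions of
#'   the first/last member CpG, 1-based inclusive), `n_cpgs`, `direction`
#'   (`"hypo"`/`"hyper"`), `mean_q`, `mean_methdiff`, `n_seeds`,
#'   `members` (list column of member positions), plus `dist_to_tss` and
#'   `gene` when annotated.
#' @export
call_dmrs <- function(results, q_threshold = 0.01, p_threshold = 0.01,
                      window = 200, min_cpgs = 3, annotation = NULL) {
  results <- as_tibble(results)
  req <- c("chrom", "pos", "p_value", "q_value", "beta")
  stopifnot(all(req %in% names(results)))
  if ("converged" %in% names(results)) {
    results <- filter(results, .data$converged)
  }
  chroms <- unique(results$chrom)
  for (ch in chroms) {
    if (is.unsorted(results$pos[results$chrom == ch], strictly = TRUE)) {
      abort(sprintf("results must be sorted by position within chromosome (%s).", ch))
    }
  }
  has_md <- "methdiff" %in% names(results)

  out <- list()
  for (ch in chroms) {
    d <- results[results$chrom == ch, ]
    seeds <- which(!is.na(d$q_value) & d$q_value < q_threshold)
    if (!length(seeds)) next
    # merge closed windows around seeds
    sp <- d$pos[seeds]
    lo <- sp - window
    hi <- sp + window
    merged <- list()
    cur_lo <- lo[1]; cur_hi <- hi[1]
    if (length(sp) > 1) {
      for (k in 2:length(sp)) {
        if (lo[k] <= cur_hi) {
          cur_hi <- max(cur_hi, hi[k])
        } else {
          merged[[length(merged) + 1L]] <- c(cur_lo, cur_hi)
          cur_lo <- lo[k]; cur_hi <- hi[k]
        }
      }
    }
    merged[[length(merged) + 1L]] <- c(cur_lo, cur_hi)

    seed_pos <- d$pos[seeds]
    for (reg in merged) {
      idx <- which(d$pos >= reg[1] & d$pos <= reg[2])
      if (length(idx) < min_cpgs) next
      ok <- !is.na(d$p_value[idx]) & d$p_value[idx] < p_threshold &
        !is.na(d$beta[idx]) & d$beta[idx] != 0
      key <- ifelse(ok, sign(d$beta[idx]), 0)
      r <- rle(key)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (seg in seq_along(r$values)) {
        if (r$values[seg] == 0 || r$lengths[seg] < min_cpgs) next
        run <- idx[starts[seg]:ends[seg]]
        run_pos <- d$pos[run]
        if (!any(seed_pos >= run_pos[1] & seed_pos <= run_pos[length(run_pos)])) next
        out[[length(out) + 1L]] <- tibble(
          chrom = ch,
          start = run_pos[1],
          end = run_pos[length(run_pos)],
          n_cpgs = length(run),
          direction = if (r$values[seg] > 0) "hyper" else "hypo",
          mean_q = mean(d$q_value[run]),
          mean_methdiff = if (has_md) mean(d$methdiff[run]) else NA_real_,
          n_seeds = sum(seed_pos >= run_pos[1] & seed_pos <= run_pos[length(run_pos)]),
          members = list(run_pos)
        )
      }
    }
  }
  dmrs <- if (length(out)) bind_rows(out) else tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), direction = character(), mean_q = numeric(),
    mean_methdiff = numeric(), n_seeds = integer(), members = list()
  )
  dmrs <- dmrs %>%
    mutate(.chrom_ord = match(.data$chrom, chroms)) %>%
    arrange(.data$.chrom_ord, .data$start) %>%
    select(-".chrom_ord")
  if (!is.null(annotation) && "tss" %in% names(annotation) && nrow(dmrs)) {
    dmrs <- .annotate_tss(dmrs, annotation$tss)
  }
  class(dmrs) <- c("dmr_result", class(dmrs))
  attr(dmrs, "q_threshold") <- q_threshold
  attr(dmrs, "p_threshold") <- p_threshold
  attr(dmrs, "window") <- window
  dmrs
}

# signed distance from the DMR midpoint to the nearest TSS, upstream
# negative relative to gene orientation
.annotate_tss <- function(dmrs, tss) {
  mid <- round((dmrs$start + dmrs$end) / 2)
  dist <- rep(NA_real_, nrow(dmrs))
  gene <- rep(NA_character_, nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    cand <- tss[tss$chrom == dmrs$chrom[i], ]
    if (!nrow(cand)) next
    delta <- mid[i] - cand$start
    j <- which.min(abs(delta))
    sgn <- if ("strand" %in% names(cand) && cand$strand[j] == "-") -1 else 1
    dist[i] <- sgn * delta[j]
    gene[i] <- if ("name" %in% names(cand)) cand$name[j] else NA_character_
  }
  dmrs$dist_to_tss <- dist
  dmrs$gene <- gene
  dmrs
}

#' Dose-directional filtering of differentially methylated CpGs
#'
#' For each CpG, the coverage-pooled methylation ratio
#' (`sum(meth) / sum(total)` over group members, masked samples
#' excluded) is computed in the ACPA-negative, medium, high and RA
#' groups. The call is `hypo` when the negative > medium > high means
#' decrease strictly, `hyper` when they increase strictly, `none`
#' otherwise; `ra_consistent` is `TRUE` when the RA group mean extends
#' the monotone trend beyond the high group (weak inequality).
#'
#' @param m A [meth_matrix()].
#' @param s Sample sheet containing all four groups.
#' @param dmcs Tibble with `chrom`, `pos` of the CpGs to classify.
#' @param strict Use strict monotonicity across the three ACPA groups
#'   (default `TRUE`; `FALSE` allows ties).
#' @return A `directional_call` tibble: `chrom`, `pos`, `mean_neg`,
#'   `mean_med`, `mean_high`, `mean_ra`, `direction`, `ra_consistent`.
#' @export
directional_filter <- function(m, s, dmcs, strict = TRUE) {
  stopifnot(inherits(m, "meth_mat"))
  s <- as_tibble(s)
  groups <- list(
    neg = !s$ra & s$acpa_group == "negative",
    med = !s$ra & s$acpa_group == "medium",
    high = !s$ra & s$acpa_group == "high",
    ra = s$ra
  )
  for (g in names(groups)) {
    if (!any(groups[[g]])) abort(sprintf("group '%s' is empty.", g))
  }
  idx <- match(paste(dmcs$chrom, dmcs$pos), paste(m$cpgs$chrom, m$cpgs$pos))
  if (anyNA(idx)) abort("some DMC positions are absent from the methylation matrix.")
  col <- match(s$sample_id, m$samples)
  pool <- function(sel) {
    jj <- col[sel]
    tm <- m$meth[idx, jj, drop = FALSE]
    tt <- m$total[idx, jj, drop = FALSE]
    rowSums(tm) / pmax(rowSums(tt), 1)
  }
  mn <- pool(groups$neg); mm <- pool(groups$med)
  mh <- pool(groups$high); mr <- pool(groups$ra)
  lt <- if (strict) `<` else `<=`
  hyper <- lt(mn, mm) & lt(mm, mh)
  hypo <- lt(mm, mn) & lt(mh, mm)
  direction <- ifelse(hyper, "hyper", ifelse(hypo, "hypo", "none"))
  ra_consistent <- (direction == "hyper" & mr >= mh) |
    (direction == "hypo" & mr <= mh)
  out <- tibble(
    chrom = dmcs$chrom, pos = dmcs$pos,
    mean_neg = mn, mean_med = mm, mean_high = mh, mean_ra = mr,
    direction = direction, ra_consistent = ra_consistent
  )
  class(out) <- c("directional_call", class(out))
  out
}

#' Compare two DMC or DMR sets
#'
#' For identifier vectors, an exact set partition with the Jaccard
#' index. For interval tables (data frames with `chrom`, `start`,
#' `end`), "shared" means an interval intersection of at least 1 bp on
#' the same chromosome; the reported coefficient is the fraction of
#' intervals (pooled over both sets) that overlap the other set, which
#' is 1 for identical sets and 0 for disjoint ones.
#'
#' @param a,b Character vectors of identifiers, or interval data frames.
#' @return A list: `shared`, `a_only`, `b_only`, `jaccard`. In interval
#'   mode `shared` is a tibble of overlapping index pairs (`a_idx`,
#'   `b_idx`) and `a_only`/`b_only` are row indices.
#' @export
compare_sets <- function(a, b) {
  if (is.data.frame(a) || is.data.frame(b)) {
    stopifnot(is.data.frame(a), is.data.frame(b))
    gra <- .track_granges(as_tibble(a))
    grb <- .track_granges(as_tibble(b))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gra, grb, ignore.strand = TRUE)
    )
    ai <- unique(S4Vectors::queryHits(hits))
    bi <- unique(S4Vectors::subjectHits(hits))
    n_a <- nrow(a); n_b <- nrow(b)
    jac <- if (n_a + n_b == 0) NA_real_ else (length(ai) + length(bi)) / (n_a + n_b)
    list(
      shared = tibble(a_idx = S4Vectors::queryHits(hits),
                      b_idx = S4Vectors::subjectHits(hits)),
      a_only = setdiff(seq_len(n_a), ai),
      b_only = setdiff(seq_len(n_b), bi),
      jaccard = jac
    )
  } else {
    shared <- intersect(a, b)
    uni <- union(a, b)
    list(
      shared = shared,
      a_only = setdiff(a, b),
      b_only = setdiff(b, a),
      jaccard = if (length(uni) == 0) NA_real_ else length(shared) / length(uni)
    )
  }
}
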