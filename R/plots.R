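#' QQ plot of EWAS p-values
#'
#' Observed versus expected -log10 p with the genomic-control lambda in
#' the subtitle.
#'
#' @param results An `ewas_result`.
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  p <- results$p_value[results$converged & !is.na(results$p_value)]
  n <- length(p)
  d <- tibble(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(p))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("genomic control lambda = %.2f", attr(results, "lambda_gc"))
    ) +
    ggplot2::theme_classic()
}

#' Manhattan plot of EWAS p-values
#'
#' @param results An `ewas_result`.
#' @param q_threshold Significance line drawn at the largest p with
#'   `q < q_threshold` (default: the run's threshold).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, q_threshold = NULL) {
  q_threshold <- q_threshold %||% attr(results, "q_threshold") %||% 0.01
  d <- as_tibble(as.data.frame(results)) %>%
    filter(.data$converged, !is.na(.data$p_value))
  chroms <- unique(d$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) max(d$pos[d$chrom == ch]), numeric(1))))
  d$x <- d$pos + offs[match(d$chrom, chroms)]
  sig_p <- suppressWarnings(max(d$p_value[!is.na(d$q_value) & d$q_value < q_threshold]))
  gg <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$x, y = -log10(.data$p_value), colour = .data$chrom
  )) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_classic()
  if (is.finite(sig_p)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(sig_p), linetype = 2)
  }
  gg
}

#' @method autoplot ewas_result
#' @export
autoplot.ewas_result <- function(object, type = c("qq", "manhattan"), ...) {
  type <- match.arg(type)
  switch(type, qq = plot_qq(object), manhattan = plot_manhattan(object))
}

#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- filter(as_tibble(object), !is.na(.data$fold_change))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$fold_change),
    y = .data$fold_change,
    fill = .data$p_value < 0.001
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold change", fill = "p < 0.001") +
    ggplot2::theme_classic()
}

#' Per-group methylation profile of a single CpG
#'
#' Jittered per-sample methylation ratios by ACPA group (plus the RA
#' group), point size proportional to read coverage, with the
#' coverage-pooled group means overlaid -- the standard display of a
#' dose-directional CpG.
#'
#' @param m A [meth_matrix()].
#' @param s Sample sheet.
#' @param chrom,pos CpG coordinates.
#' @return A ggplot object.
#' @export
plot_dose_profile <- function(m, s, chrom, pos) {
  i <- which(m$cpgs$chrom == chrom & m$cpgs$pos == pos)
  if (!length(i)) abort("CpG not found in the methylation matrix.")
  s <- as_tibble(s)
  j <- match(s$sample_id, m$samples)
  d <- tibble(
    group = factor(
      ifelse(s$ra, "RA", s$acpa_group),
      levels = c("negative", "medium", "high", "RA")
    ),
    total = m$total[i, j],
    ratio = ifelse(m$total[i, j] > 0, m$meth[i, j] / m$total[i, j], NA_real_)
  ) %>% filter(!is.na(.data$ratio))
  means <- d %>%
    group_by(.data$group) %>%
    summarise(mean_ratio = sum(.data$ratio * .data$total) / sum(.data$total),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_jitter(ggplot2::aes(size = .data$total), width = 0.15,
                         alpha = 0.5) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(y = .data$mean_ratio),
                        colour = "red", shape = 95, size = 10) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::labs(x = NULL, y = "methylation ratio", size = "coverage",
                  title = sprintf("%s:%d", chrom, pos)) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
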