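#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an EWAS result
#'
#' @param x An `ewas_result` from [run_ewas()].
#' @param ... Unused.
#' @return A plain tibble (one row per CpG).
#' @method tidy ewas_result
#' @export
tidy.ewas_result <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of an EWAS run
#'
#' @param x An `ewas_result`.
#' @param ... Unused.
#' @return A one-row tibble: model name, CpGs tested, genomic-control
#'   lambda, Storey pi0, DMC counts (total / hypo / hyper at the run's
#'   q threshold), failed fits.
#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, ...) {
  tibble(
    model = attr(x, "model"),
    n_tested = attr(x, "n_tested"),
    lambda_gc = attr(x, "lambda_gc"),
    pi0 = attr(x, "pi0"),
    q_threshold = attr(x, "q_threshold"),
    n_dmc = attr(x, "n_dmc"),
    n_hypo = attr(x, "n_hypo"),
    n_hyper = attr(x, "n_hyper"),
    n_failed = attr(x, "n_failed")
  )
}

#' @export
print.ewas_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ewas_result> model %s: %d CpGs tested, lambda_GC = %.3f, pi0 = %.3f\n",
    g$model, g$n_tested, g$lambda_gc, g$pi0
  ))
  cat(sprintf(
    " DMCs at q < %g: %d (%d hypo / %d hyper); %d failed fits\n",
    g$q_threshold, g$n_dmc, g$n_hypo, g$n_hyper, g$n_failed
  ))
  NextMethod()
}

#' Tidy a Storey q-value fit
#'
#' @param x A `qvalue_fit` from [estimate_qvalues()].
#' @param ... Unused.
#' @return Tibble of the lambda grid and raw pi0 estimates.
#' @method tidy qvalue_fit
#' @export
tidy.qvalue_fit <- function(x, ...) {
  tibble(lambda = x$lambda, pi0_lambda = x$pi0_lambda)
}

#' @rdname tidy.qvalue_fit
#' @method glance qvalue_fit
#' @export
glance.qvalue_fit <- function(x, ...) {
  tibble(pi0 = x$pi0, m = x$m)
}

#' One-row summary of a cis-meQTL scan
#'
#' @param x A `meqtl_result` from [map_cis_meqtls()].
#' @param ... Unused.
#' @return Tibble with pair counts, genome-wide significant counts, and
#'   the numbers of distinct CpGs/SNPs involved.
#' @method glance meqtl_result
#' @export
glance.meqtl_result <- function(x, ...) {
  gw <- x$gw_significant
  tibble(
    n_pairs_tested = attr(x, "n_pairs_tested"),
    n_pairs_skipped = attr(x, "n_pairs_skipped"),
    n_cpgs_selected = attr(x, "n_cpgs_selected"),
    n_gw_pairs = sum(gw),
    n_gw_cpgs = dplyr::n_distinct(paste(x$cpg_chrom, x$cpg_pos)[gw]),
    n_gw_snps = dplyr::n_distinct(x$snp_id[gw]),
    window = attr(x, "window")
  )
}

#' One-row summary of a gDMR/ngDMR classification
#'
#' @param x A `genetic_classification` from [adjust_and_classify()].
#' @param ... Unused.
#' @return Tibble of label counts and the number of refitted DMCs.
#' @method glance genetic_classification
#' @export
glance.genetic_classification <- function(x, ...) {
  tibble(
    n_dmrs = nrow(x),
    n_gdmr = sum(x$label == "gDMR"),
    n_ngdmr = sum(x$label == "ngDMR"),
    n_untestable = sum(x$label == "untestable"),
    n_dmcs_refitted = attr(x, "n_refitted")
  )
}

#' @method glance replication_result
#' @export
glance.replication_result <- function(x, ...) as_tibble(as.data.frame(x))
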