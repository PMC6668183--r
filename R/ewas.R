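#' EWAS model specifications
#'
#' The five model specifications:
#' \describe{
#'   \item{I}{ACPA-positive vs ACPA-negative (RA subjects excluded);
#'     covariates age, sex, smoking.}
#'   \item{II}{Model I plus the five measured blood-cell proportions.}
#'   \item{III}{Self-reported RA vs all other subjects; covariates age,
#'     sex, smoking, cell proportions.}
#'   \item{IV}{ACPA dose as an ordinal 0/1/2 numeric predictor
#'     (negative/medium/high; RA subjects excluded); covariates as II.}
#'   \item{V}{Case vs control with no covariates (validation-cohort
#'     model); the predictor is the `case` column if present, else `ra`.}
#' }
#' Smoking enters as two indicators (current, past; never = reference);
#' the basophil proportion is dropped as the cell-composition reference
#' to keep the design full rank (the five proportions sum to 1).
#'
#' @param name One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @return A list of class `model_spec` with elements `name`,
#'   `predictor`, `covariates`, and contrast group definitions.
#' @export
model_spec <- function(name = c("I", "II", "III", "IV", "V")) {
  name <- match.arg(name)
  base_covs <- c("age", "sex", "smoking")
  cells <- c("monocyte", "lymphocyte", "neutrophil", "eosinophil")
  spec <- switch(name,
    I = list(predictor = "acpa_pos", covariates = base_covs,
             contrast = "acpa_positive", reference = "acpa_negative",
             exclude_ra = TRUE),
    II = list(predictor = "acpa_pos", covariates = c(base_covs, cells),
              contrast = "acpa_positive", reference = "acpa_negative",
              exclude_ra = TRUE),
    III = list(predictor = "ra", covariates = c(base_covs, cells),
               contrast = "ra", reference = "non_ra", exclude_ra = FALSE),
    IV = list(predictor = "dose", covariates = c(base_covs, cells),
              contrast = "acpa_high", reference = "acpa_negative",
              exclude_ra = TRUE),
    V = list(predictor = "case", covariates = character(0),
             contrast = "case", reference = "control", exclude_ra = FALSE)
  )
  structure(c(list(name = name), spec), class = "model_spec")
}

# Build the design matrix and sample mask for a model spec.
.build_design <- function(s, spec) {
  s <- as_tibble(s)
  keep <- if (isTRUE(spec$exclude_ra) && "ra" %in% names(s)) !s$ra else rep(TRUE, nrow(s))
  s <- s[keep, , drop = FALSE]
  x <- switch(spec$predictor,
    acpa_pos = as.numeric(s$acpa_group != "negative"),
    dose = c(negative = 0, medium = 1, high = 2)[s$acpa_group],
    ra = as.numeric(s$ra),
    case = as.numeric(if ("case" %in% names(s)) s$case else s$ra)
  )
  if (length(unique(x)) < 2) {
    abort(sprintf("predictor '%s' is constant on the selected samples.", spec$predictor))
  }
  X <- cbind(`(Intercept)` = 1, predictor = unname(x))
  for (cv in spec$covariates) {
    X <- switch(cv,
      sex = cbind(X, sexM = as.numeric(s$sex == "M")),
      smoking = cbind(X,
        smoking_current = as.numeric(s$smoking == "current"),
        smoking_past = as.numeric(s$smoking == "past")
      ),
      cbind(X, setNames(data.frame(s[[cv]]), cv) %>% as.matrix())
    )
  }
  # drop covariate columns that are constant on these samples
  keep_col <- c(TRUE, TRUE, vapply(
    seq_len(ncol(X) - 2) + 2L,
    function(j) length(unique(X[, j])) > 1, logical(1)
  ))
  list(X = X[, keep_col, drop = FALSE], samples = s)
}

# Core weighted-binomial IRLS fit for one CpG.
# Returns beta/se/z/p for the column named `target` plus convergence flag.
.fit_one <- function(X, meth, total, target = "predictor") {
  keep <- total > 0
  n_used <- sum(keep)
  Xk <- X[keep, , drop = FALSE]
  y <- meth[keep] / total[keep]
  w <- total[keep]
  # drop columns (other than intercept and target) constant on this subset
  fixed <- colnames(Xk) %in% c("(Intercept)", target)
  keep_col <- fixed | apply(Xk, 2, function(col) length(unique(col)) > 1)
  Xk <- Xk[, keep_col, drop = FALSE]
  if (length(unique(Xk[, target])) < 2) {
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                n_used = n_used, converged = FALSE))
  }
  fit <- tryCatch(
    suppressWarnings(glm.fit(
      Xk, y, weights = w, family = binomial(),
      control = list(epsilon = 1e-14, maxit = 100)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$rank < ncol(Xk)) {
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                n_used = n_used, converged = FALSE))
  }
  p_rank <- fit$rank
  R <- fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE]
  cov_unscaled <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(p_rank)]
  se_all <- rep(NA_real_, ncol(Xk))
  se_all[piv] <- sqrt(diag(cov_unscaled))
  j <- match(target, colnames(Xk))
  beta <- fit$coefficients[j]
  se <- se_all[j]
  ok <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    is.finite(beta) && is.finite(se) && se < 100
  z <- beta / se
  list(beta = unname(beta), se = unname(se), z = unname(z),
       p = 2 * pnorm(-abs(z)), n_used = n_used, converged = ok)
}

#' Fit one binomial (logit) count regression
#'
#' Maximum-likelihood grouped-binomial logistic fit via iteratively
#' reweighted least squares: the response is the per-sample methylation
#' proportion `meth / total` weighted by `total`, so for a two-group
#' design without covariates the fitted coefficient equals the
#' difference of pooled logits exactly. The Wald statistic is
#' `z = beta / se` with a two-sided normal p-value.
#'
#' @param data Data frame with count columns and predictor/covariate
#'   columns, one row per sample.
#' @param target Name of the predictor of interest.
#' @param covariates Character vector of adjustment columns (numeric or
#'   two-level factors/characters, expanded via [stats::model.matrix()]).
#' @param meth_col,total_col Names of the methylated / total count
#'   columns.
#' @return A one-row tibble: `beta`, `se`, `wald_z`, `p_value`, `n_used`,
#'   `direction`, `converged`.
#' @export
fit_binomial_glm <- function(data, target, covariates = character(0),
                             meth_col = "meth", total_col = "total") {
  data <- as_tibble(data)
  stopifnot(all(c(meth_col, total_col, target) %in% names(data)))
  keep <- data[[total_col]] > 0
  if (length(unique(data[[target]][keep])) < 2) {
    abort(sprintf("predictor '%s' must take at least two distinct values.", target))
  }
  rhs <- paste(c(target, covariates), collapse = " + ")
  X <- stats::model.matrix(
    stats::as.formula(paste("~", rhs)),
    data = data
  )
  target_col <- colnames(X)[attr(X, "assign") == 1][1]
  qrX <- qr(X[keep, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  res <- .fit_one(X, data[[meth_col]], data[[total_col]], target = target_col)
  tibble(
    beta = res$beta, se = res$se, wald_z = res$z, p_value = res$p,
    n_used = res$n_used, direction = sign(res$beta %||% NA_real_),
    converged = res$converged
  )
}

#' Run a per-CpG binomial-regression EWAS
#'
#' Fits the chosen model at every CpG, computes Wald p-values, Storey
#' q-values over the converged autosomal tests, pooled contrast/reference
#' group methylation ratios, and the genomic-control inflation factor.
#' Per-CpG fit failures (non-convergence, separation, constant predictor
#' after masking) are retained as `converged = FALSE` rows excluded from
#' the FDR computation; the scan never aborts on them.
#'
#' @param m A filtered [meth_matrix()].
#' @param s Sample sheet (see [read_sample_sheet()]); for model V a
#'   minimal sheet with `sample_id` and `case`/`ra` suffices.
#' @param model Model name (`"I"`..`"V"`) or a [model_spec()].
#' @param q_threshold Significance threshold on q (default 0.01).
#' @return An `ewas_result` tibble (one row per CpG): `chrom`, `pos`,
#'   `beta`, `se`, `wald_z`, `p_value`, `q_value`, `n_used`, `direction`,
#'   `converged`, `ratio_ref`, `ratio_contrast`, `methdiff`. Attributes:
#'   `model`, `lambda_gc`, `pi0`, `q_threshold`, `n_dmc`, `n_hypo`,
#'   `n_hyper`, `n_failed`.
#' @export
run_ewas <- function(m, s, model = "II", q_threshold = 0.01) {
  stopifnot(inherits(m, "meth_mat"))
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  d <- .build_design(s, spec)
  idx <- match(d$samples$sample_id, m$samples)
  if (anyNA(idx)) abort("sample sheet contains samples absent from the methylation matrix.")
  meth <- m$meth[, idx, drop = FALSE]
  total <- m$total[, idx, drop = FALSE]
  X <- d$X
  n_cpg <- nrow(m$cpgs)

  beta <- se <- z <- p <- rep(NA_real_, n_cpg)
  n_used <- integer(n_cpg)
  conv <- logical(n_cpg)
  for (i in seq_len(n_cpg)) {
    r <- .fit_one(X, meth[i, ], total[i, ])
    beta[i] <- r$beta; se[i] <- r$se; z[i] <- r$z; p[i] <- r$p
    n_used[i] <- r$n_used; conv[i] <- r$converged
  }

  # pooled group methylation ratios for the contrast of interest
  grp <- .contrast_groups(d$samples, spec)
  pool <- function(sel) {
    tm <- meth[, sel, drop = FALSE]; tt <- total[, sel, drop = FALSE]
    rowSums(tm) / pmax(rowSums(tt), 1)
  }
  ratio_contrast <- pool(grp$contrast)
  ratio_ref <- pool(grp$reference)

  q <- rep(NA_real_, n_cpg)
  auto <- !(m$cpgs$chrom %in% c("chrX", "chrY", "X", "Y"))
  usable <- conv & auto & !is.na(p)
  qfit <- NULL
  if (any(usable)) {
    qfit <- estimate_qvalues(p[usable])
    q[usable] <- qfit$q
  }
  lam <- if (any(usable)) genomic_lambda(p[usable]) else NA_real_

  sig <- !is.na(q) & q < q_threshold
  out <- tibble(
    chrom = m$cpgs$chrom, pos = m$cpgs$pos,
    beta = beta, se = se, wald_z = z, p_value = p, q_value = q,
    n_used = n_used, direction = sign(beta), converged = conv,
    ratio_ref = ratio_ref, ratio_contrast = ratio_contrast,
    methdiff = ratio_contrast - ratio_ref
  )
  structure(
    out,
    class = c("ewas_result", class(out)),
    model = spec$name, lambda_gc = lam,
    pi0 = if (!is.null(qfit)) qfit$pi0 else NA_real_,
    q_threshold = q_threshold,
    n_tested = sum(usable), n_failed = sum(!conv),
    n_dmc = sum(sig), n_hypo = sum(sig & beta < 0), n_hyper = sum(sig & beta > 0)
  )
}

.contrast_groups <- function(s, spec) {
  switch(spec$name,
    I = ,
    II = list(contrast = s$acpa_group != "negative",
              reference = s$acpa_group == "negative"),
    III = list(contrast = s$ra, reference = !s$ra),
    IV = list(contrast = s$acpa_group == "high",
              reference = s$acpa_group == "negative"),
    V = {
      x <- if ("case" %in% names(s)) s$case else s$ra
      list(contrast = as.logical(x), reference = !as.logical(x))
    }
  )
}

#' Storey q-values
#'
#' The null proportion pi0 is estimated as `#{p > lambda} / (m (1 -
#' lambda))` on the grid lambda = 0.05, 0.10, ..., 0.90, smoothed with a
#' natural cubic spline (3 df) and evaluated at lambda = 0.90, clamped to
#' (0, 1]. Then `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j`, which is
#' monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed null proportion overriding the estimate
#'   (e.g. `pi0 = 1` gives Benjamini-Hochberg adjusted p-values).
#' @return A list of class `qvalue_fit`: `q` (q-values in input order),
#'   `pi0`, `lambda` (grid), `pi0_lambda` (raw estimates), `m`.
#' @export
estimate_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) abort("p-value vector is empty.")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  m <- length(p)
  lambda <- seq(0.05, 0.90, by = 0.05)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (is.null(pi0)) {
    pi0_hat <- if (m >= 100) {
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      predict(fit, x = 0.90)$y
    } else {
      # too few tests for a stable spline; fall back to the conservative
      # BH choice
      1
    }
    pi0 <- min(max(pi0_hat, 1e-4), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) abort("pi0 must lie in (0, 1].")
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(
    list(q = q, pi0 = pi0, lambda = lambda, pi0_lambda = pi0_lambda, m = m),
    class = "qvalue_fit"
  )
}

#' @export
print.qvalue_fit <- function(x, ...) {
  cat("<qvalue_fit> m =", x$m, " pi0 =", signif(x$pi0, 4), "\n")
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`;
#' values near 1 indicate no inflation of the test statistics.
#'
#' @param p Numeric vector of p-values.
#' @return The inflation factor (scalar).
#' @export
genomic_lambda <- function(p) {
  if (length(p) == 0) abort("p-value vector is empty.")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq, na.rm = TRUE) / qchisq(0.5, df = 1)
}
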