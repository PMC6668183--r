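# Independent reference implementations used to freeze expected values.
# These deliberately use closed forms / exhaustive enumeration, not the
# package's own code paths.

# pooled-logit closed form for a two-group binomial fit without covariates
oracle_two_group_fit <- function(meth0, total0, meth1, total1) {
  m0 <- sum(meth0); t0 <- sum(total0)
  m1 <- sum(meth1); t1 <- sum(total1)
  beta <- log(m1 / (t1 - m1)) - log(m0 / (t0 - m0))
  se <- sqrt(1 / m0 + 1 / (t0 - m0) + 1 / m1 + 1 / (t1 - m1))
  list(beta = beta, se = se)
}

# exhaustive maximal-run enumerator for the DMR definition
oracle_dmrs <- function(d, q_threshold = 0.01, p_threshold = 0.01,
                        window = 200, min_cpgs = 3) {
  out <- list()
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, ]
    x <- x[order(x$pos), ]
    seeds <- x$pos[!is.na(x$q_value) & x$q_value < q_threshold]
    if (!length(seeds)) next
    # merged candidate intervals around seeds (closed)
    iv <- cbind(sort(seeds) - window, sort(seeds) + window)
    merged <- list(iv[1, ])
    for (k in seq_len(nrow(iv))[-1]) {
      last <- merged[[length(merged)]]
      if (iv[k, 1] <= last[2]) {
        merged[[length(merged)]][2] <- max(last[2], iv[k, 2])
      } else {
        merged[[length(merged) + 1]] <- iv[k, ]
      }
    }
    region_of <- rep(NA_integer_, nrow(x))
    for (r in seq_along(merged)) {
      region_of[x$pos >= merged[[r]][1] & x$pos <= merged[[r]][2]] <- r
    }
    ok <- !is.na(x$p_value) & x$p_value < p_threshold &
      !is.na(x$beta) & x$beta != 0
    dir <- ifelse(ok, sign(x$beta), 0)
    n <- nrow(x)
    is_seed <- !is.na(x$q_value) & x$q_value < q_threshold
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < min_cpgs) next
        span <- i:j
        if (anyNA(region_of[span]) ||
            length(unique(region_of[span])) != 1) next
        if (any(dir[span] == 0) || length(unique(dir[span])) != 1) next
        # maximality within the candidate region
        left_ext <- i > 1 && !is.na(region_of[i - 1]) &&
          region_of[i - 1] == region_of[i] && dir[i - 1] == dir[i]
        right_ext <- j < n && !is.na(region_of[j + 1]) &&
          region_of[j + 1] == region_of[j] && dir[j + 1] == dir[j]
        if (left_ext || right_ext) next
        if (!any(is_seed[span])) next
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = x$pos[i], end = x$pos[j],
          n_cpgs = j - i + 1,
          direction = if (dir[i] > 0) "hyper" else "hypo"
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# two-sided Fisher p by direct hypergeometric enumeration (lchoose
# arithmetic; sums all tables at most as probable as the observed one)
oracle_fisher_p <- function(k, n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  xs <- lo:hi
  logp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  p_obs <- logp[xs == k]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# random small EWAS-like result table for DMR oracle fuzzing
random_dmr_instance <- function(n = NULL) {
  n <- n %||% sample(5:50, 1)
  pos <- sort(sample.int(3000, n))
  p <- 10^runif(n, -4, 0)
  tibble::tibble(
    chrom = "chr1",
    pos = pos,
    p_value = p,
    q_value = pmin(p * runif(n, 0.3, 3), 1),
    beta = stats::rnorm(n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
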