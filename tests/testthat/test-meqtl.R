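# helper: one-CpG methylation matrix with ratios encoded at 1/1000
# resolution, plus a genotype matrix, for controlled regression checks
meqtl_fixture <- function(ratio, dosage, cpg_pos = 1000, snp_pos = 2000) {
  n <- length(ratio)
  ids <- sprintf("s%03d", seq_len(n))
  m <- meth_matrix(
    tibble::tibble(chrom = "chr1", pos = cpg_pos),
    matrix(round(ratio * 1000), 1, n), matrix(1000, 1, n), ids
  )
  g <- geno_matrix(
    tibble::tibble(chrom = "chr1", pos = snp_pos, id = "rs1", ref = "A",
                   alt = "G", biallelic = TRUE),
    matrix(dosage, 1, n), matrix(30, 1, n), ids
  )
  list(m = m, g = g)
}

test_that("per-pair OLS agrees with lm() on random small instances", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    dos <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (length(unique(dos)) < 2) next
    ratio <- round(runif(n), 3)
    fx <- meqtl_fixture(ratio, dos)
    res <- map_cis_meqtls(fx$m, fx$g)
    ref <- summary(lm(ratio ~ dos))$coefficients
    expect_equal(res$slope, unname(ref["dos", "Estimate"]), tolerance = 1e-8)
    expect_equal(res$t_stat, unname(ref["dos", "t value"]), tolerance = 1e-8)
    expect_equal(res$p_value, unname(ref["dos", "Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("the planted per-allele slope is recovered", {
  set.seed(43)
  n <- 100
  dos <- rbinom(n, 2, 0.4)
  ratio <- pmin(pmax(0.1 + 0.2 * dos + rnorm(n, 0, 0.01), 0), 1)
  fx <- meqtl_fixture(ratio, dos)
  res <- map_cis_meqtls(fx$m, fx$g)
  expect_equal(res$slope, 0.2, tolerance = 0.01 / 0.2)
  expect_lt(res$p_value, 1e-10)
})

test_that("the cis window is a hard 250-kb bound", {
  set.seed(44)
  dos <- rbinom(60, 2, 0.4)
  ratio <- round(runif(60), 3)
  far <- meqtl_fixture(ratio, dos, cpg_pos = 1000, snp_pos = 1000 + 260000)
  expect_equal(nrow(map_cis_meqtls(far$m, far$g)), 0)
  edge <- meqtl_fixture(ratio, dos, cpg_pos = 1000, snp_pos = 1000 + 250000)
  expect_equal(nrow(map_cis_meqtls(edge$m, edge$g)), 1)
})

test_that("constant dosage or methylation is skipped, not an error", {
  fx <- meqtl_fixture(round(runif(30), 3), rep(1, 30))
  res <- map_cis_meqtls(fx$m, fx$g)
  expect_equal(nrow(res), 0)
  expect_gte(attr(res, "n_pairs_skipped"), 1)
})

test_that("CpG selection applies the call-rate and variance rules", {
  n <- 20
  ids <- sprintf("s%03d", seq_len(n))
  # CpG 1: full coverage, high variance; CpG 2: covered in 8/20 (<50%);
  # CpG 3: full coverage, near-zero variance (below the median)
  total <- rbind(rep(50, n), c(rep(50, 8), rep(0, 12)), rep(50, n))
  meth <- rbind(round(seq(0, 49, length.out = n)),
                c(rep(25, 8), rep(0, 12)),
                c(rep(25, n - 1), 26))
  m <- meth_matrix(tibble::tibble(chrom = "chr1", pos = c(100, 200, 300)),
                   meth, total, ids)
  set.seed(45)
  g <- geno_matrix(
    tibble::tibble(chrom = "chr1", pos = 500, id = "rs1", ref = "A",
                   alt = "G", biallelic = TRUE),
    matrix(rbinom(n, 2, 0.5), 1, n), matrix(30, 1, n), ids
  )
  res <- map_cis_meqtls(m, g)
  expect_equal(attr(res, "n_cpgs_selected"), 1)
  expect_equal(unique(res$cpg_pos), 100)
})

test_that("an uncorrelated genotype covariate leaves the effect estimate alone", {
  set.seed(47)
  n <- 120
  group <- rep(0:1, each = n / 2)
  total <- rep(40, n)
  p <- plogis(-0.2 + 0.8 * group)
  meth <- rbinom(n, total, p)
  dos <- rbinom(n, 2, 0.3)  # independent of group and methylation
  d <- tibble::tibble(meth = meth, total = total, group = group, dos = dos)
  fit0 <- fit_binomial_glm(d, "group")
  fit1 <- fit_binomial_glm(d, "group", covariates = "dos")
  expect_lt(abs(fit1$beta - fit0$beta), 0.1)
  expect_lt(abs(fit1$se - fit0$se) / fit0$se, 0.1)
})

test_that("confounded and genuine planted regions are classified correctly", {
  pl <- default_pipeline()
  truth <- pl$sim$truth$dmrs
  cls <- pl$cls
  margin <- 2100  # island half-width + SNP offset slack
  lab_true <- vapply(seq_len(nrow(cls)), function(i) {
    hit <- truth[truth$chrom == cls$chrom[i] &
                   truth$start - margin <= cls$end[i] &
                   truth$end + margin >= cls$start[i], ]
    if (nrow(hit) == 0) "none" else hit$mechanism[1]
  }, character(1))
  known <- lab_true != "none"
  correct <- (cls$label == "gDMR" & lab_true == "genotype-confounded") |
    (cls$label == "ngDMR" & lab_true == "dose")
  expect_gte(mean(correct[known]), 0.8)
  # refit bookkeeping is coherent
  ref <- dmc_refits(cls)
  expect_true(all(ref$p_bonferroni[ref$refitted] >=
                    ref$p_adj_raw[ref$refitted] - 1e-12))
  expect_true(all(cls$label %in% c("gDMR", "ngDMR", "untestable")))
  expect_true(all(cls$n_testable[cls$label == "untestable"] == 0))
})
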