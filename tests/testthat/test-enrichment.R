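toy_annotation <- function() {
  feature_annotation(
    cgi = tibble::tibble(chrom = "chr1", start = 10000, end = 11000),
    genes = tibble::tibble(chrom = "chr1", start = 9000, end = 30000,
                           strand = "+", name = "G1"),
    tss = tibble::tibble(chrom = "chr1", start = 20000, end = 20000,
                         strand = "+", name = "G1"),
    exons = tibble::tibble(chrom = "chr1", start = 10500, end = 10700,
                           strand = "+", name = "G1")
  )
}

test_that("CGI class follows the distance to the nearest island edge", {
  ann <- toy_annotation()
  cpgs <- tibble::tibble(
    chrom = "chr1",
    pos = c(10500, 11500, 13000, 13500, 15000, 16000)
    # inside, 500 out (shore), 2000 out (shore edge), 2500 out (shelf),
    # 4000 out (shelf edge), 5000 out (open sea)
  )
  fc <- annotate_features(cpgs, ann)
  expect_equal(fc$cgi_class,
               c("cgi", "shore", "shore", "shelf", "shelf", "open_sea"))
  # partition is exhaustive and disjoint
  expect_true(all(fc$cgi + fc$cgi_shore + fc$cgi_shelf + fc$open_sea == 1))
})

test_that("promoter windows and flag independence behave as defined", {
  ann <- toy_annotation()
  fc <- annotate_features(
    tibble::tibble(chrom = "chr1", pos = c(18800, 18000, 10600)), ann
  )
  expect_equal(fc$tss1500, c(TRUE, FALSE, FALSE))  # 1200 vs 2000 bp upstream
  # CpG inside a CGI that also lies in an exon carries both flags
  expect_true(fc$cgi[3] && fc$exon[3])
  # intergenic only outside gene bodies and promoter windows
  expect_false(fc$intergenic[1])
})

test_that("CpGs on chromosomes absent from the annotation warn and flag false", {
  ann <- toy_annotation()
  expect_warning(
    fc <- annotate_features(tibble::tibble(chrom = "chr9", pos = 100), ann),
    "absent"
  )
  expect_false(fc$cgi[1])
  expect_equal(fc$cgi_class[1], "open_sea")
})

test_that("shore/shelf partition holds on simulated data", {
  st <- small_study()
  cpgs <- st$sim$methylation$cpgs[seq_len(500), ]
  fc <- annotate_features(cpgs, st$sim$annotation)
  expect_true(all(fc$cgi + fc$cgi_shore + fc$cgi_shelf + fc$open_sea == 1))
})

test_that("Fisher enrichment equals exhaustive hypergeometric enumeration", {
  set.seed(53)
  for (i in 1:200) {
    N <- sample(20:200, 1)
    n <- sample(5:(N - 5), 1)
    K <- sample(1:(N - 1), 1)
    # draw an observed k consistent with the margins
    k <- sample(max(0, n + K - N):min(n, K), 1)
    tab <- matrix(c(k, n - k, K - k, (N - K) - (n - k)), 2, 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 oracle_fisher_p(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("the worked 2x2 table gives fold 5 and the enumerated p", {
  # build CpG sets realising k=10, n=20, K=100, N=1000 for one feature
  cpgs <- tibble::tibble(chrom = "chr1", pos = seq_len(1000) * 10)
  ann <- feature_annotation(
    myfeat = tibble::tibble(chrom = "chr1", start = 1, end = 1000)
  )  # positions 10..1000: the first 100 CpGs
  dmr <- cpgs[c(1:10, 901:910), ]
  res <- feature_enrichment(dmr, cpgs, ann, features = "myfeat")
  expect_equal(res$k, 10)
  expect_equal(res$K, 100)
  expect_equal(res$fold_change, 5.0)
  expect_equal(res$p_value, oracle_fisher_p(10, 20, 100, 1000),
               tolerance = 1e-12)
})

test_that("equal proportions give fold 1 and an empty feature reports NA", {
  cpgs <- tibble::tibble(chrom = "chr1", pos = seq_len(1000) * 10)
  ann <- feature_annotation(
    feat = tibble::tibble(chrom = "chr1", start = 1, end = 1000),
    nothing = tibble::tibble(chrom = "chr2", start = 1, end = 10)
  )
  dmr <- cpgs[c(1:10, 101:190), ]  # 10/100 in feature vs 100/1000 overall
  res <- feature_enrichment(dmr, cpgs, ann)
  feat <- res[res$feature == "feat", ]
  expect_equal(feat$fold_change, 1.0)
  expect_gt(feat$p_value, 0.9)
  none <- res[res$feature == "nothing", ]
  expect_true(is.na(none$fold_change))
  expect_equal(none$p_value, 1)
  expect_error(feature_enrichment(cpgs[0, ], cpgs, ann), "empty")
  expect_error(
    feature_enrichment(tibble::tibble(chrom = "chr1", pos = 99999), cpgs, ann),
    "subset"
  )
})

test_that("replication handles empty discovery sets and missing overlap", {
  disc <- tibble::tibble(
    chrom = "chr1", pos = 1:50, p_value = runif(50, 0.5, 1),
    q_value = runif(50, 0.5, 1), direction = 1
  )
  val <- tibble::tibble(
    chrom = "chr1", pos = 1:50, p_value = runif(50), direction = 1
  )
  r <- replicate_ewas(disc, val)
  expect_equal(r$replication_rate, 0)
  expect_true(is.na(r$fold_enrichment))
  expect_equal(r$p_value, 1)
  off <- val
  off$chrom <- "chr9"
  expect_error(replicate_ewas(disc, off), "common")
})

test_that("shared planted effects replicate across cohorts", {
  rp <- replication_pair()
  r <- replicate_ewas(rp$disc, rp$val_res)
  expect_gt(r$fold_enrichment, 3)
  expect_lt(r$p_value, 1e-4)
  expect_gt(r$n_replicated, 0)
  expect_true(r$n_replicated <= r$n_discovery_dmcs_tested)
  expect_true(r$n_discovery_dmcs_tested <= r$n_common_tested)

  # DMR-level replication of the planted regions
  dmrs <- call_dmrs(rp$disc)
  rd <- replicate_dmrs(dmrs, rp$val_res)
  expect_gt(attr(rd, "replication_rate"), 0.5)
})

test_that("label-permuted validation results show no enrichment", {
  rp <- replication_pair()
  set.seed(59)
  folds <- replicate(50, {
    perm <- sample(nrow(rp$val_res))
    shuf <- tidy(rp$val_res)
    shuf$p_value <- shuf$p_value[perm]
    shuf$direction <- shuf$direction[perm]
    shuf$converged <- shuf$converged[perm]
    replicate_ewas(rp$disc, shuf)$fold_enrichment
  })
  expect_gt(mean(folds), 0.9)
  expect_lt(mean(folds), 1.1)
})

test_that("the standard displays build without error", {
  st <- small_study()
  res <- run_ewas(st$flt$methylation[seq_len(200), ], st$sim$samples, "II")
  expect_s3_class(plot_qq(res), "ggplot")
  expect_s3_class(autoplot(res, type = "manhattan"), "ggplot")
  cpg <- res[which.min(res$p_value), ]
  expect_s3_class(
    plot_dose_profile(st$flt$methylation, st$sim$samples, cpg$chrom, cpg$pos),
    "ggplot"
  )
  enr <- feature_enrichment(
    st$sim$methylation$cpgs[1:50, ], st$sim$methylation$cpgs,
    st$sim$annotation
  )
  expect_s3_class(autoplot(enr), "ggplot")
})
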