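test_that("the worked seed-and-merge example yields one three-member DMR", {
  d <- tibble::tibble(
    chrom = "chr1",
    pos = c(100, 150, 220, 500),
    p_value = c(0.001, 0.005, 0.009, 0.2),
    q_value = c(0.5, 0.004, 0.5, 0.9),
    beta = c(1, 1, 1, 1)
  )
  dmrs <- call_dmrs(d)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 100)
  expect_equal(dmrs$end, 220)
  expect_equal(dmrs$n_cpgs, 3)
  expect_equal(dmrs$direction, "hyper")
})

test_that("two qualifying CpGs or a sign break never form a DMR", {
  two <- tibble::tibble(
    chrom = "chr1", pos = c(100, 150),
    p_value = c(0.001, 0.002), q_value = c(0.001, 0.002), beta = c(1, 1)
  )
  expect_equal(nrow(call_dmrs(two)), 0)
  flip <- tibble::tibble(
    chrom = "chr1", pos = c(100, 150, 200),
    p_value = rep(0.001, 3), q_value = rep(0.001, 3), beta = c(1, -1, 1)
  )
  expect_equal(nrow(call_dmrs(flip)), 0)
})

test_that("unsorted input is rejected", {
  d <- tibble::tibble(
    chrom = "chr1", pos = c(200, 100),
    p_value = c(0.001, 0.001), q_value = c(0.001, 0.001), beta = c(1, 1)
  )
  expect_error(call_dmrs(d), "sorted")
})

test_that("the caller agrees with brute-force enumeration on random instances", {
  set.seed(17)
  for (i in 1:1000) {
    inst <- random_dmr_instance()
    got <- call_dmrs(inst)
    want <- oracle_dmrs(inst)
    got_key <- sprintf("%s:%d-%d:%s:%d", got$chrom, got$start, got$end,
                       got$direction, got$n_cpgs)
    want_key <- sprintf("%s:%d-%d:%s:%d", want$chrom, want$start, want$end,
                        want$direction, want$n_cpgs)
    expect_identical(sort(got_key), sort(want_key))
    # structural invariants on every emitted DMR
    expect_true(all(got$n_cpgs >= 3))
    expect_true(all(got$n_seeds >= 1))
  }
})

test_that("DMR output is invariant to chromosome processing order", {
  set.seed(23)
  a <- random_dmr_instance(40)
  b <- random_dmr_instance(40)
  b$chrom <- "chr2"
  fwd <- call_dmrs(dplyr::bind_rows(a, b))
  rev <- call_dmrs(dplyr::bind_rows(b, a))
  key <- function(x) sort(sprintf("%s:%d-%d", x$chrom, x$start, x$end))
  expect_identical(key(fwd), key(rev))
})

test_that("planted regions are recovered with few false discoveries", {
  pl <- default_pipeline()
  truth <- pl$sim$truth$dmrs
  dmrs <- pl$dmrs
  hit <- mapply(
    function(ch, s, e) any(dmrs$chrom == ch & dmrs$start <= e & dmrs$end >= s),
    truth$chrom, truth$start, truth$end
  )
  false_call <- !mapply(
    function(ch, s, e) any(truth$chrom == ch & truth$start <= e & truth$end >= s),
    dmrs$chrom, dmrs$start, dmrs$end
  )
  expect_gte(mean(hit), 0.8)
  expect_lte(mean(false_call), 0.2)
  # every emitted DMR respects the membership invariants
  expect_true(all(dmrs$n_cpgs >= 3))
  expect_true(all(dmrs$n_seeds >= 1))
  expect_true(all(dmrs$direction %in% c("hypo", "hyper")))
})

test_that("directional calls follow the pooled group means", {
  mk <- function(means) {
    # 8 samples: 2 per group, totals 100, exact ratios
    cpgs <- tibble::tibble(chrom = "chr1", pos = 50)
    total <- matrix(100, 1, 8)
    meth <- matrix(rep(round(means * 100), each = 2), 1, 8)
    m <- meth_matrix(cpgs, meth, total, paste0("s", 1:8))
    s <- tibble::tibble(
      sample_id = paste0("s", 1:8),
      acpa_group = rep(c("negative", "medium", "high", "negative"), each = 2),
      ra = rep(c(FALSE, FALSE, FALSE, TRUE), each = 2)
    )
    directional_filter(m, s, tibble::tibble(chrom = "chr1", pos = 50))
  }
  hypo <- mk(c(0.50, 0.45, 0.40, 0.35))
  expect_equal(hypo$direction, "hypo")
  expect_true(hypo$ra_consistent)

  flat <- mk(c(0.5, 0.5, 0.5, 0.5))
  expect_equal(flat$direction, "none")
  expect_false(flat$ra_consistent)

  bump <- mk(c(0.50, 0.55, 0.52, 0.50))
  expect_equal(bump$direction, "none")
})

test_that("directional filtering requires all four groups", {
  cpgs <- tibble::tibble(chrom = "chr1", pos = 50)
  m <- meth_matrix(cpgs, matrix(5, 1, 2), matrix(10, 1, 2), c("a", "b"))
  s <- tibble::tibble(sample_id = c("a", "b"),
                      acpa_group = c("negative", "high"),
                      ra = c(FALSE, FALSE))
  expect_error(directional_filter(m, s, cpgs), "empty")
})

test_that("set comparison handles identifiers and intervals", {
  ids <- compare_sets(c("a", "b"), c("a", "b"))
  expect_equal(ids$jaccard, 1)
  expect_length(ids$a_only, 0)
  disj <- compare_sets(c("a"), c("b"))
  expect_equal(disj$jaccard, 0)
  expect_length(disj$shared, 0)

  iv <- compare_sets(
    data.frame(chrom = "chr1", start = 100, end = 200),
    data.frame(chrom = "chr1", start = 150, end = 300)
  )
  expect_equal(nrow(iv$shared), 1)
  expect_equal(iv$jaccard, 1)
  off <- compare_sets(
    data.frame(chrom = "chr1", start = 100, end = 200),
    data.frame(chrom = "chr2", start = 150, end = 300)
  )
  expect_equal(nrow(off$shared), 0)
})
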