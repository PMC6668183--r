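# Expensive shared fixtures, built once per test run. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# full default-scale study (the package's reference simulation) run
# through the whole pipeline; used by the DMR-recovery, classification
# and end-to-end checks
default_pipeline <- function() {
  fixture("default_pipeline", {
    t_start <- Sys.time()
    sim <- simulate_dataset(simulate_config(seed = 101))
    flt <- filter_cpgs(sim$methylation)
    res <- run_ewas(flt$methylation, sim$samples, "IV")
    dmrs <- call_dmrs(res, annotation = sim$annotation)
    geno <- filter_snps(sim$genotypes)$genotypes
    meqtls <- map_cis_meqtls(sim$methylation, geno)
    dmcs <- dplyr::filter(tidy(res), !is.na(q_value), q_value < 0.01)
    cls <- adjust_and_classify(dmcs, dmrs, meqtls, flt$methylation,
                               sim$samples, geno, "IV")
    enr <- feature_enrichment(
      dmcs[, c("chrom", "pos")],
      tidy(res)[, c("chrom", "pos")],
      sim$annotation
    )
    val <- simulate_validation(sim, seed = 102)
    val_res <- run_ewas(val$methylation, val$samples, "V")
    repl <- replicate_ewas(res, val_res)
    elapsed <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    list(sim = sim, filtered = flt, res = res, dmrs = dmrs, geno = geno,
         meqtls = meqtls, dmcs = dmcs, cls = cls, enr = enr,
         val = val, val_res = val_res, repl = repl, elapsed = elapsed)
  })
}

# null study (no planted effects) at the calibration problem size
null_run <- function() {
  fixture("null_run", {
    cfg <- simulate_config(
      n_neg = 65, n_med = 45, n_high = 20, n_ra = 0, n_cpgs = 5000,
      n_true_dmrs = 0, n_confounded_dmrs = 0, effect_logit = 0, seed = 11
    )
    sim <- simulate_dataset(cfg)
    flt <- filter_cpgs(sim$methylation)
    res <- run_ewas(flt$methylation, sim$samples, "II")
    list(sim = sim, res = res)
  })
}

# small study for cheap structural tests
small_study <- function() {
  fixture("small_study", {
    sim <- simulate_dataset(simulate_config(
      n_cpgs = 2000, n_true_dmrs = 4, n_confounded_dmrs = 2, seed = 42
    ))
    flt <- filter_cpgs(sim$methylation)
    list(sim = sim, flt = flt)
  })
}

# pooled high-vs-negative methylation difference per planted dose
# region, signed by the planted direction
planted_pooled_diff <- function(sim) {
  truth <- sim$truth
  m <- sim$methylation
  s <- sim$samples
  neg <- !s$ra & s$acpa_group == "negative"
  high <- !s$ra & s$acpa_group == "high"
  dose <- truth$dmrs[truth$dmrs$mechanism == "dose", ]
  vapply(seq_len(nrow(dose)), function(k) {
    rows <- which(!is.na(truth$baseline$island) &
                    truth$baseline$island == dose$island[k])
    ph <- sum(m$meth[rows, high]) / sum(m$total[rows, high])
    pn <- sum(m$meth[rows, neg]) / sum(m$total[rows, neg])
    (ph - pn) * if (dose$direction[k] == "hyper") 1 else -1
  }, numeric(1))
}

# discovery/validation cohort pair sharing 50 planted regions, for the
# replication statistics
replication_pair <- function() {
  fixture("replication_pair", {
    sim <- simulate_dataset(simulate_config(
      n_cpgs = 5000, n_true_dmrs = 50, n_confounded_dmrs = 0, seed = 77
    ))
    disc <- run_ewas(filter_cpgs(sim$methylation)$methylation,
                     sim$samples, "IV")
    val <- simulate_validation(sim, seed = 78)
    val_res <- run_ewas(val$methylation, val$samples, "V")
    list(sim = sim, disc = disc, val_res = val_res)
  })
}
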