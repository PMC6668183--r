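#' Configuration for the synthetic MCC-Seq study generator
#'
#' Defaults reproduce the design of the emulated study: 66 ACPA-negative,
#' 45 medium-positive and 18 high-positive subjects without RA (63
#' ACPA-positive in total) plus 8 self-reported RA subjects, mean targeted
#' coverage 15x, and planted effect regions for parameter-recovery tests.
#'
#' @param n_neg,n_med,n_high Numbers of non-RA subjects per ACPA group
#'   (negative / medium-positive / high-positive).
#' @param n_ra Number of self-reported RA subjects (all female; 3/4
#'   ACPA-positive, the rest negative, mirroring the emulated cohort).
#' @param n_cpgs Total number of simulated CpGs (including the chrX CpGs
#'   that exist solely to exercise the sex-chromosome filter).
#' @param n_chroms Number of autosomes; one "chrX" is always added.
#' @param mean_coverage Expected reads per CpG per sample (negative
#'   binomial mean).
#' @param coverage_dispersion Negative-binomial size parameter of the
#'   coverage distribution (smaller = more overdispersed).
#' @param n_true_dmrs Number of planted regions whose methylation responds
#'   directly to ACPA dose ("dose" mechanism).
#' @param n_confounded_dmrs Number of planted regions whose methylation is
#'   driven purely by a cis SNP whose allele frequency differs between
#'   ACPA groups ("genotype-confounded" mechanism).
#' @param effect_logit ACPA-dose effect per ordinal step (0/1/2) on the
#'   logit scale at dose-mechanism CpGs.
#' @param cell_effect_logit Logit-scale effect per unit deviation of the
#'   neutrophil proportion from its cohort mean (applies to every CpG).
#' @param meqtl_slope_logit Logit-scale methylation change per alt allele
#'   at the cis SNP attached to each dose-mechanism region (gives genuine
#'   regions a real, phenotype-independent meQTL). Set to 0 to disable.
#' @param confounded_slope_logit Logit-scale per-allele effect at
#'   genotype-confounded regions.
#' @param overdispersion_rho Intra-CpG beta-binomial correlation; 0 means
#'   pure binomial sampling.
#' @param planted_baseline_logit Baseline logit methylation of planted
#'   regions. `NULL` (default) draws region baselines from N(0, 0.3) with
#'   per-CpG jitter; a scalar fixes every planted CpG's baseline exactly.
#' @param confound_cells If `TRUE`, the neutrophil proportion increases
#'   with ACPA dose so that cell composition confounds unadjusted models.
#' @param confound_covariates If `TRUE`, current smoking becomes more
#'   frequent at higher ACPA dose (for covariate-adjustment tests).
#' @param seed Integer random seed; identical seeds give identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
simulate_config <- function(n_neg = 66, n_med = 45, n_high = 18, n_ra = 8,
                            n_cpgs = 50000, n_chroms = 4,
                            mean_coverage = 15, coverage_dispersion = 5,
                            n_true_dmrs = 20, n_confounded_dmrs = 20,
                            effect_logit = 1.0, cell_effect_logit = 2.0,
                            meqtl_slope_logit = 0.8,
                            confounded_slope_logit = 1.2,
                            overdispersion_rho = 0,
                            planted_baseline_logit = NULL,
                            confound_cells = FALSE,
                            confound_covariates = FALSE,
                            seed = 1L) {
  cfg <- list(
    n_neg = n_neg, n_med = n_med, n_high = n_high, n_ra = n_ra,
    n_cpgs = n_cpgs, n_chroms = n_chroms,
    mean_coverage = mean_coverage, coverage_dispersion = coverage_dispersion,
    n_true_dmrs = n_true_dmrs, n_confounded_dmrs = n_confounded_dmrs,
    effect_logit = effect_logit, cell_effect_logit = cell_effect_logit,
    meqtl_slope_logit = meqtl_slope_logit,
    confounded_slope_logit = confounded_slope_logit,
    overdispersion_rho = overdispersion_rho,
    planted_baseline_logit = planted_baseline_logit,
    confound_cells = confound_cells,
    confound_covariates = confound_covariates,
    seed = as.integer(seed)
  )
  counts <- c(n_neg, n_med, n_high, n_ra)
  if (any(counts < 0)) abort("group sizes must be non-negative.")
  if (n_neg + n_med + n_high < 2) abort("need at least two non-RA subjects.")
  if (n_neg < 1 || (n_med + n_high) < 1) {
    abort("both ACPA-negative and ACPA-positive groups must be non-empty.")
  }
  if (n_cpgs < 100) abort("n_cpgs must be at least 100.")
  if (n_chroms < 1) abort("need at least one autosome.")
  if (mean_coverage <= 0) abort("mean_coverage must be positive.")
  if (coverage_dispersion <= 0) abort("coverage_dispersion must be positive.")
  if (n_true_dmrs < 0 || n_confounded_dmrs < 0) abort("planted region counts must be non-negative.")
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    abort("overdispersion_rho must be in [0, 1).")
  }
  structure(cfg, class = "sim_config")
}

# ACPA optical densities: log-normal within group, truncated at the
# clinical thresholds (<=20 negative, 20-60 medium, >60 high).
.draw_acpa_od <- function(group, n) {
  pars <- switch(group,
    negative = list(lo = 0, hi = 20, meanlog = log(8), sdlog = 0.6),
    medium = list(lo = 20, hi = 60, meanlog = log(35), sdlog = 0.4),
    high = list(lo = 60, hi = Inf, meanlog = log(80), sdlog = 0.5)
  )
  plo <- plnorm(pars$lo, pars$meanlog, pars$sdlog)
  phi <- if (is.finite(pars$hi)) plnorm(pars$hi, pars$meanlog, pars$sdlog) else 1
  round(qlnorm(runif(n, plo, phi), pars$meanlog, pars$sdlog), 1)
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

.simulate_samples <- function(cfg) {
  n_pos_ra <- round(0.75 * cfg$n_ra)
  groups <- c(
    rep("negative", cfg$n_neg), rep("medium", cfg$n_med), rep("high", cfg$n_high),
    # RA subjects: 3/4 ACPA-positive (split medium/high), rest negative
    rep(c("medium", "high"), length.out = n_pos_ra),
    rep("negative", cfg$n_ra - n_pos_ra)
  )
  ra <- c(rep(FALSE, cfg$n_neg + cfg$n_med + cfg$n_high), rep(TRUE, cfg$n_ra))
  n <- length(groups)
  dose <- c(negative = 0, medium = 1, high = 2)[groups]
  gen_dose <- ifelse(ra, 3, dose)  # RA extends the dose trend beyond "high"

  smoke_p <- t(vapply(dose, function(d) {
    if (cfg$confound_covariates) {
      p_cur <- 0.1 + 0.15 * d
      c(p_cur, 0.42, 1 - 0.42 - p_cur)
    } else {
      c(0.20, 0.42, 0.38)
    }
  }, numeric(3)))
  smoking <- vapply(
    seq_len(n),
    function(i) sample(c("current", "past", "never"), 1, prob = smoke_p[i, ]),
    character(1)
  )
  alpha0 <- c(monocyte = 8, lymphocyte = 30, neutrophil = 55, eosinophil = 5, basophil = 2)
  cells <- matrix(NA_real_, n, 5, dimnames = list(NULL, names(alpha0)))
  for (i in seq_len(n)) {
    a <- alpha0
    if (cfg$confound_cells) a["neutrophil"] <- a["neutrophil"] * (1 + 0.4 * gen_dose[i])
    cells[i, ] <- .rdirichlet(1, a)
  }
  od <- numeric(n)
  for (g in c("negative", "medium", "high")) {
    idx <- which(groups == g)
    od[idx] <- .draw_acpa_od(g, length(idx))
  }
  tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    acpa_od = od,
    acpa_group = groups,
    ra = ra,
    age = round(runif(n, 40, 70), 1),
    sex = ifelse(ra, "F", ifelse(runif(n) < 0.63, "F", "M")),
    smoking = smoking,
    monocyte = cells[, "monocyte"],
    lymphocyte = cells[, "lymphocyte"],
    neutrophil = cells[, "neutrophil"],
    eosinophil = cells[, "eosinophil"],
    basophil = cells[, "basophil"],
    .dose = dose,
    .gen_dose = gen_dose
  )
}

# CpG map: clustered islands + dispersed background per autosome, plus a
# background-only chrX to exercise the sex-chromosome filter.
.simulate_cpg_map <- function(cfg) {
  chrom_len <- 1e7
  n_x <- max(50, round(0.02 * cfg$n_cpgs))
  n_auto_total <- cfg$n_cpgs - n_x
  autosomes <- paste0("chr", seq_len(cfg$n_chroms))
  per_chrom <- diff(round(seq(0, n_auto_total, length.out = cfg$n_chroms + 1)))

  cpg_list <- list()
  island_list <- list()
  isl_id <- 0L
  for (ci in seq_along(autosomes)) {
    chrom <- autosomes[ci]
    n_c <- per_chrom[ci]
    n_islands <- max(2L, round(0.4 * n_c / 12))
    slots <- seq(2e5, chrom_len - 2e5, by = 2e4)  # >= 20 kb apart
    centers <- sort(sample(slots, min(n_islands, length(slots))))
    isl_cpgs <- list()
    for (k in seq_along(centers)) {
      isl_id <- isl_id + 1L
      size <- 5L + stats::rpois(1, 7)
      w <- runif(1, 400, 1200)
      pos <- sort(unique(round(centers[k] + runif(size, -w / 2, w / 2))))
      isl_cpgs[[k]] <- tibble(
        chrom = chrom, pos = pos, island = isl_id, in_island = TRUE
      )
      island_list[[isl_id]] <- tibble(
        island = isl_id, chrom = chrom,
        start = min(pos) - 50, end = max(pos) + 50, center = centers[k]
      )
    }
    isl_tab <- bind_rows(isl_cpgs)
    n_bg <- max(0L, n_c - nrow(isl_tab))
    bg <- tibble(
      chrom = chrom,
      pos = sort(sample.int(chrom_len, n_bg)),
      island = NA_integer_, in_island = FALSE
    )
    cpg_list[[chrom]] <- bind_rows(isl_tab, bg) %>%
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
      arrange(.data$pos)
  }
  cpg_list[["chrX"]] <- tibble(
    chrom = "chrX", pos = sort(sample.int(chrom_len, n_x)),
    island = NA_integer_, in_island = FALSE
  )
  list(
    cpgs = bind_rows(cpg_list),
    islands = bind_rows(island_list),
    chrom_len = chrom_len,
    autosomes = autosomes
  )
}

#' Generate a complete synthetic MCC-Seq-like study
#'
#' Produces methylation counts, a sample sheet, genotypes, genomic
#' annotations and the ground truth of every planted effect. The count
#' model: total reads per CpG per sample are negative binomial; the
#' per-sample methylation probability is
#' `inv_logit(baseline + effect * dose + cell_effect * (neutrophil - mean) +
#' slope * genotype)`, with methylated reads binomial (or beta-binomial
#' when `overdispersion_rho > 0`). Genotypes are Hardy-Weinberg draws;
#' planted regions are CpG islands carrying either a direct dose effect
#' (plus a phenotype-independent cis meQTL) or a purely genotype-driven
#' effect whose allele frequency differs between ACPA groups.
#'
#' @param config A [simulate_config()] object.
#' @return A list of class `sim_study` with elements `methylation`
#'   ([meth_matrix()]), `samples` (tibble), `genotypes` ([geno_matrix()]),
#'   `annotation` ([feature_annotation()]) and `truth` (list with `dmrs`,
#'   `meqtl_pairs`, `baseline`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  samples <- .simulate_samples(cfg)
  n_samp <- nrow(samples)
  map <- .simulate_cpg_map(cfg)
  cpgs <- map$cpgs
  islands <- map$islands
  n_cpg <- nrow(cpgs)

  n_plant <- cfg$n_true_dmrs + cfg$n_confounded_dmrs
  if (n_plant > nrow(islands)) {
    abort(sprintf(
      "requested %d planted regions but only %d CpG islands were simulated; increase n_cpgs.",
      n_plant, nrow(islands)
    ))
  }
  planted_islands <- sample(islands$island, n_plant)
  mech <- rep(c("dose", "genotype-confounded"),
              c(cfg$n_true_dmrs, cfg$n_confounded_dmrs))
  plant <- tibble(
    island = planted_islands,
    mechanism = mech[sample.int(n_plant)],
    direction = sample(c(-1, 1), n_plant, replace = TRUE)
  )

  # baseline logit methylation: planted islands partially methylated,
  # other islands hypomethylated, background hypermethylated
  base <- numeric(n_cpg)
  bg_idx <- which(!cpgs$in_island)
  base[bg_idx] <- rnorm(length(bg_idx), 2.2, 0.6)
  for (isl in unique(cpgs$island[cpgs$in_island])) {
    idx <- which(!is.na(cpgs$island) & cpgs$island == isl)
    if (isl %in% plant$island) {
      if (is.null(cfg$planted_baseline_logit)) {
        base[idx] <- rnorm(1, 0, 0.3) + rnorm(length(idx), 0, 0.15)
      } else {
        base[idx] <- cfg$planted_baseline_logit
      }
    } else {
      base[idx] <- rnorm(1, -2.5, 0.5) + rnorm(length(idx), 0, 0.3)
    }
  }

  # SNPs: one cis SNP per planted region + dispersed background SNPs
  snp_rows <- list()
  dose_freq <- c(0.2, 0.35, 0.5)  # allele frequency per ACPA dose at confounded SNPs
  for (r in seq_len(nrow(plant))) {
    isl <- islands[islands$island == plant$island[r], ]
    offset <- sample(500:2000, 1) * sample(c(-1, 1), 1)
    slope <- plant$direction[r] *
      if (plant$mechanism[r] == "genotype-confounded") cfg$confounded_slope_logit else cfg$meqtl_slope_logit
    snp_rows[[length(snp_rows) + 1L]] <- tibble(
      chrom = isl$chrom,
      pos = pmax(1, round(isl$center + offset)),
      island = plant$island[r],
      mechanism = plant$mechanism[r],
      slope_logit = slope,
      base_freq = runif(1, 0.15, 0.45)
    )
  }
  n_bg_snps <- max(20L, round(cfg$n_cpgs / 1000))
  for (chrom in map$autosomes) {
    k <- ceiling(n_bg_snps / length(map$autosomes))
    snp_rows[[length(snp_rows) + 1L]] <- tibble(
      chrom = chrom, pos = sort(sample.int(map$chrom_len, k)),
      island = NA_integer_, mechanism = "none",
      slope_logit = 0, base_freq = runif(k, 0.1, 0.5)
    )
  }
  snps <- bind_rows(snp_rows) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    arrange(match(.data$chrom, map$autosomes), .data$pos) %>%
    mutate(id = sprintf("snp%04d", dplyr::row_number()))
  bases <- c("A", "C", "G", "T")
  snps$ref <- sample(bases, nrow(snps), replace = TRUE)
  snps$alt <- vapply(snps$ref, function(b) sample(setdiff(bases, b), 1), character(1))

  # genotypes: HWE draws; confounded SNPs use dose-dependent frequencies
  # (RA subjects draw at the high-dose frequency)
  dosage <- matrix(NA_real_, nrow(snps), n_samp)
  eff_dose <- pmin(samples$.gen_dose, 2)
  for (i in seq_len(nrow(snps))) {
    freq <- if (snps$mechanism[i] == "genotype-confounded") {
      dose_freq[eff_dose + 1]
    } else {
      rep(snps$base_freq[i], n_samp)
    }
    dosage[i, ] <- rbinom(n_samp, 2, freq)
  }
  depth <- matrix(
    rnbinom(nrow(snps) * n_samp, mu = cfg$mean_coverage * 1.3,
            size = cfg$coverage_dispersion),
    nrow(snps), n_samp
  )
  genotypes <- geno_matrix(
    select(snps, "chrom", "pos", "id", "ref", "alt"),
    dosage, depth, samples$sample_id
  )

  # per-CpG per-sample methylation probability
  plant_cpg <- left_join(
    tibble(island = cpgs$island),
    plant, by = "island"
  )
  isl2snp <- snps %>%
    filter(!is.na(.data$island)) %>%
    select("island", "id")
  snp_row_of_island <- setNames(match(isl2snp$id, snps$id), isl2snp$island)

  eta <- matrix(rep(base, n_samp), n_cpg, n_samp)
  cell_dev <- samples$neutrophil - mean(samples$neutrophil)
  eta <- eta + cfg$cell_effect_logit * matrix(rep(cell_dev, each = n_cpg), n_cpg, n_samp)
  dose_vec <- samples$.gen_dose
  for (r in seq_len(nrow(plant))) {
    idx <- which(!is.na(cpgs$island) & cpgs$island == plant$island[r])
    srow <- snp_row_of_island[[as.character(plant$island[r])]]
    slope <- snps$slope_logit[srow]
    g <- dosage[srow, ]
    if (plant$mechanism[r] == "dose") {
      eta[idx, ] <- eta[idx, ] +
        outer(rep(plant$direction[r] * cfg$effect_logit, length(idx)), dose_vec) +
        outer(rep(slope, length(idx)), g)
    } else {
      eta[idx, ] <- eta[idx, ] + outer(rep(slope, length(idx)), g)
    }
  }
  p <- inv_logit(eta)

  total <- matrix(
    rnbinom(n_cpg * n_samp, mu = cfg$mean_coverage, size = cfg$coverage_dispersion),
    n_cpg, n_samp
  )
  if (cfg$overdispersion_rho > 0) {
    rho <- cfg$overdispersion_rho
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    p <- matrix(rbeta(n_cpg * n_samp, a, b), n_cpg, n_samp)
  }
  meth <- matrix(rbinom(n_cpg * n_samp, total, p), n_cpg, n_samp)
  meth[total == 0] <- 0L

  methylation <- meth_matrix(
    select(cpgs, "chrom", "pos"), meth, total, samples$sample_id
  )

  annotation <- .simulate_annotation(cfg, map, snps)

  truth_dmrs <- plant %>%
    left_join(islands, by = "island") %>%
    left_join(isl2snp %>% rename(snp_id = "id"), by = "island") %>%
    mutate(
      n_cpgs = vapply(
        .data$island,
        function(i) sum(!is.na(cpgs$island) & cpgs$island == i), integer(1)
      ),
      direction = ifelse(.data$direction > 0, "hyper", "hypo")
    ) %>%
    select("chrom", "start", "end", "direction", "mechanism", "island",
           "snp_id", "n_cpgs")
  meqtl_pairs <- truth_dmrs %>%
    rename(region_chrom = "chrom") %>%
    purrr::pmap(function(region_chrom, start, end, direction, mechanism,
                         island, snp_id, n_cpgs) {
      idx <- which(!is.na(cpgs$island) & cpgs$island == island)
      tibble(
        snp_id = snp_id,
        cpg_chrom = cpgs$chrom[idx],
        cpg_pos = cpgs$pos[idx],
        slope_logit = snps$slope_logit[match(snp_id, snps$id)]
      )
    }) %>%
    bind_rows()

  structure(
    list(
      methylation = methylation,
      samples = select(samples, -".dose", -".gen_dose"),
      genotypes = genotypes,
      annotation = annotation,
      truth = list(
        dmrs = truth_dmrs,
        meqtl_pairs = meqtl_pairs,
        baseline = tibble(chrom = cpgs$chrom, pos = cpgs$pos, logit0 = base,
                          island = cpgs$island)
      ),
      config = cfg
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>\n")
  print(x$methylation)
  cat(" samples: ", nrow(x$samples), "  genotyped SNPs: ",
      nrow(x$genotypes$snps), "\n", sep = "")
  cat(" planted regions: ", nrow(x$truth$dmrs), " (",
      sum(x$truth$dmrs$mechanism == "dose"), " dose, ",
      sum(x$truth$dmrs$mechanism == "genotype-confounded"),
      " genotype-confounded)\n", sep = "")
  invisible(x)
}

# gene models + CGI + autoimmune tracks for the simulated genome
.simulate_annotation <- function(cfg, map, snps) {
  cgi <- map$islands %>% select("chrom", "start", "end")
  gene_rows <- list()
  for (chrom in map$autosomes) {
    n_genes <- 30L
    starts <- sort(sample(seq(1e5, map$chrom_len - 2e5, by = 1e4), n_genes))
    len <- round(runif(n_genes, 5e3, 5e4))
    gene_rows[[chrom]] <- tibble(
      chrom = chrom, start = starts, end = pmin(starts + len, map$chrom_len),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      name = paste0("GENE_", chrom, "_", seq_len(n_genes))
    )
  }
  genes <- bind_rows(gene_rows)
  tss_pos <- ifelse(genes$strand == "+", genes$start, genes$end)
  tes_pos <- ifelse(genes$strand == "+", genes$end, genes$start)
  tss <- tibble(chrom = genes$chrom, start = tss_pos, end = tss_pos,
                strand = genes$strand, name = genes$name)
  tes <- tibble(chrom = genes$chrom, start = tes_pos, end = tes_pos,
                strand = genes$strand, name = genes$name)

  exon_rows <- list()
  for (i in seq_len(nrow(genes))) {
    n_ex <- sample(3:8, 1)
    bounds <- round(seq(genes$start[i], genes$end[i], length.out = n_ex + 1))
    ex <- tibble(
      chrom = genes$chrom[i],
      start = bounds[-length(bounds)],
      end = pmin(bounds[-length(bounds)] + 150, bounds[-1]),
      strand = genes$strand[i], name = genes$name[i]
    )
    exon_rows[[i]] <- ex
  }
  exons <- bind_rows(exon_rows)
  first_exons <- exons %>%
    group_by(.data$name) %>%
    slice(ifelse(dplyr::first(.data$strand) == "+", 1, n())) %>%
    ungroup()
  introns <- exons %>%
    group_by(.data$chrom, .data$name, .data$strand) %>%
    summarise(
      intron_start = list(head(.data$end + 1, -1)),
      intron_end = list(tail(.data$start - 1, -1)),
      .groups = "drop"
    ) %>%
    rename(start = "intron_start", end = "intron_end") %>%
    tidyr::unnest(c("start", "end")) %>%
    filter(.data$start <= .data$end) %>%
    select("chrom", "start", "end", "strand", "name")
  utr5 <- tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$start, genes$end - 100),
    end = ifelse(genes$strand == "+", genes$start + 100, genes$end),
    strand = genes$strand, name = genes$name
  )
  utr3 <- tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$end - 100, genes$start),
    end = ifelse(genes$strand == "+", genes$end, genes$start + 100),
    strand = genes$strand, name = genes$name
  )
  # autoimmune-SNP regions: 200 bp up/downstream of a subset of SNPs
  ai_snps <- snps[sample.int(nrow(snps), max(1, round(0.3 * nrow(snps)))), ]
  autoimmune <- tibble(
    chrom = ai_snps$chrom,
    start = pmax(1, ai_snps$pos - 200),
    end = ai_snps$pos + 200,
    name = ai_snps$id
  ) %>% arrange(.data$chrom, .data$start)

  feature_annotation(
    cgi = cgi, genes = genes, tss = tss, tes = tes, exons = exons,
    first_exons = first_exons, introns = introns, utr5 = utr5, utr3 = utr3,
    autoimmune = autoimmune
  )
}

#' Simulate an independent validation cohort sharing planted effects
#'
#' Emulates the CD4+ T-cell RA case/control validation design: a new,
#' smaller cohort measured over the same CpG map, where cases carry the
#' planted dose-mechanism effects (shifted by `case_effect_logit` in the
#' planted direction) and genotype-confounded regions do not replicate.
#'
#' @param study A `sim_study` from [simulate_dataset()].
#' @param n_cases,n_controls Cohort sizes (defaults 9 RA cases, 13
#'   controls).
#' @param case_effect_logit Logit-scale case-vs-control shift at planted
#'   dose-mechanism CpGs; defaults to twice the study's per-step dose
#'   effect (the high-vs-negative contrast magnitude).
#' @param mean_coverage,coverage_dispersion Coverage model; default to the
#'   discovery configuration.
#' @param seed Integer seed.
#' @return A list with `methylation` ([meth_matrix()]) and `samples`
#'   (tibble with logical `case` and matching `ra` columns).
#' @export
simulate_validation <- function(study, n_cases = 9, n_controls = 13,
                                case_effect_logit = NULL,
                                mean_coverage = NULL,
                                coverage_dispersion = NULL, seed = 1L) {
  stopifnot(inherits(study, "sim_study"))
  cfg <- study$config
  case_effect_logit <- case_effect_logit %||% (2 * cfg$effect_logit)
  mean_coverage <- mean_coverage %||% cfg$mean_coverage
  coverage_dispersion <- coverage_dispersion %||% cfg$coverage_dispersion
  set.seed(as.integer(seed))

  baseline <- study$truth$baseline
  n_cpg <- nrow(baseline)
  n <- n_cases + n_controls
  case <- rep(c(TRUE, FALSE), c(n_cases, n_controls))

  eta <- matrix(rep(baseline$logit0, n), n_cpg, n)
  dose_regions <- study$truth$dmrs %>% filter(.data$mechanism == "dose")
  for (r in seq_len(nrow(dose_regions))) {
    idx <- which(!is.na(baseline$island) &
                   baseline$island == dose_regions$island[r])
    dir <- if (dose_regions$direction[r] == "hyper") 1 else -1
    eta[idx, case] <- eta[idx, case] + dir * case_effect_logit
  }
  p <- inv_logit(eta)
  total <- matrix(
    rnbinom(n_cpg * n, mu = mean_coverage, size = coverage_dispersion),
    n_cpg, n
  )
  meth <- matrix(rbinom(n_cpg * n, total, p), n_cpg, n)
  meth[total == 0] <- 0L
  ids <- sprintf("V%03d", seq_len(n))
  list(
    methylation = meth_matrix(select(baseline, "chrom", "pos"), meth, total, ids),
    samples = tibble(sample_id = ids, case = case, ra = case)
  )
}
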