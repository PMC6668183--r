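#' Read Bismark-coverage methylation count files
#'
#' Each file is the Bismark coverage dialect: tab-separated
#' `chrom, start (1-based), end, methylation%, count_methylated,
#' count_unmethylated`. The methylation% column is ignored in favour of
#' the counts. The result is the union of CpGs across samples; a CpG
#' absent from a sample is encoded as `total = 0`.
#'
#' @param paths Character vector of per-sample file paths.
#' @param sample_ids Sample identifiers, same length/order as `paths`;
#'   defaults to the file base names.
#' @return A [meth_matrix()].
#' @export
read_methylation_counts <- function(paths, sample_ids = NULL) {
  if (length(paths) == 0) abort("at least one coverage file is required.")
  sample_ids <- sample_ids %||% sub("\\.cov(\\.gz)?$", "", basename(paths))
  if (length(sample_ids) != length(paths)) {
    abort("`sample_ids` must match `paths` in length.")
  }
  per_sample <- lapply(seq_along(paths), function(i) {
    .read_one_cov(paths[i])
  })
  keys <- lapply(per_sample, function(d) paste(d$chrom, d$pos, sep = ":"))
  all_tab <- bind_rows(per_sample) %>%
    distinct(.data$chrom, .data$pos) %>%
    arrange(.data$chrom, .data$pos)
  all_keys <- paste(all_tab$chrom, all_tab$pos, sep = ":")
  n_cpg <- nrow(all_tab)
  meth <- matrix(0L, n_cpg, length(paths))
  total <- matrix(0L, n_cpg, length(paths))
  for (i in seq_along(per_sample)) {
    j <- match(keys[[i]], all_keys)
    meth[j, i] <- per_sample[[i]]$meth
    total[j, i] <- per_sample[[i]]$total
  }
  meth_matrix(all_tab, meth, total, sample_ids)
}

.read_one_cov <- function(path) {
  d <- tryCatch(
    suppressWarnings(readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "pct", "n_meth", "n_unmeth"),
      col_types = "ciidii", progress = FALSE,
      na = character()  # no silent NA coercion
    )),
    error = function(e) abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
  )
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed line %d in '%s': expected the Bismark coverage dialect.",
      probs$row[1], path
    ))
  }
  if (ncol(d) != 6) abort(sprintf("'%s': expected 6 tab-separated columns.", path))
  bad <- which(d$n_meth < 0 | d$n_unmeth < 0 | is.na(d$n_meth) | is.na(d$n_unmeth))
  if (length(bad)) {
    abort(sprintf("negative or missing count at line %d of '%s'.", bad[1], path))
  }
  dup <- which(duplicated(paste(d$chrom, d$start)))
  if (length(dup)) {
    abort(sprintf("duplicate position %s:%d at line %d of '%s'.",
                  d$chrom[dup[1]], d$start[dup[1]], dup[1], path))
  }
  tibble(chrom = d$chrom, pos = d$start, meth = d$n_meth,
         total = d$n_meth + d$n_unmeth)
}

#' Write a methylation matrix as per-sample Bismark coverage files
#'
#' Only covered observations (`total > 0`) are written, as in real
#' Bismark output; a CpG covered in no sample is therefore dropped by a
#' write/read round trip.
#'
#' @param m A [meth_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (one `<sample_id>.cov` each).
#' @export
write_methylation_counts <- function(m, dir) {
  stopifnot(inherits(m, "meth_mat"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(m$samples, ".cov"))
  for (j in seq_along(m$samples)) {
    keep <- m$total[, j] > 0
    d <- data.frame(
      chrom = m$cpgs$chrom[keep],
      start = m$cpgs$pos[keep],
      end = m$cpgs$pos[keep],
      pct = round(100 * m$meth[keep, j] / m$total[keep, j], 6),
      n_meth = m$meth[keep, j],
      n_unmeth = m$total[keep, j] - m$meth[keep, j]
    )
    readr::write_tsv(d, paths[j], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

.sample_sheet_cols <- c(
  "sample_id", "acpa_od", "acpa_group", "ra", "age", "sex", "smoking",
  "monocyte", "lymphocyte", "neutrophil", "eosinophil", "basophil"
)

#' Read or write the TSV sample sheet
#'
#' Columns (in order): `sample_id`, `acpa_od` (optical density units),
#' `acpa_group` (negative/medium/high), `ra` (logical), `age`, `sex`
#' (F/M), `smoking` (current/past/never) and the five measured blood-cell
#' proportions (`monocyte`, `lymphocyte`, `neutrophil`, `eosinophil`,
#' `basophil`). Validation: proportions in \[0, 1\] summing to 1 +/- 0.01
#' and `acpa_group` consistent with the OD thresholds (<=20 / 20-60 /
#' >60).
#'
#' @param path TSV file path.
#' @return `read_sample_sheet()` returns a validated tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_sample_sheet(s)
}

#' @rdname read_sample_sheet
#' @param s Sample sheet data frame.
#' @export
write_sample_sheet <- function(s, path) {
  s <- validate_sample_sheet(s)
  readr::write_tsv(s, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(s) {
  s <- as_tibble(s)
  missing_cols <- setdiff(.sample_sheet_cols, names(s))
  if (length(missing_cols)) {
    abort(paste0("sample sheet is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  cells <- as.matrix(s[, c("monocyte", "lymphocyte", "neutrophil",
                           "eosinophil", "basophil")])
  if (any(cells < 0 | cells > 1)) abort("cell proportions must lie in [0, 1].")
  if (any(abs(rowSums(cells) - 1) > 0.01)) {
    abort("cell proportions must sum to 1 within 0.01 per sample.")
  }
  expected <- ifelse(s$acpa_od <= 20, "negative",
                     ifelse(s$acpa_od <= 60, "medium", "high"))
  if (!all(s$acpa_group == expected)) {
    abort("acpa_group inconsistent with acpa_od thresholds (<=20 / 20-60 / >60).")
  }
  if (!all(s$acpa_group %in% c("negative", "medium", "high"))) {
    abort("acpa_group must be negative/medium/high.")
  }
  if (!all(s$sex %in% c("F", "M"))) abort("sex must be F or M.")
  if (!all(s$smoking %in% c("current", "past", "never"))) {
    abort("smoking must be current/past/never.")
  }
  s$ra <- as.logical(s$ra)
  s
}

#' Read genotypes from a VCF file
#'
#' Requires VCF v4.x with `GT` in FORMAT; `DP` is retained when present
#' (depth 0 where absent). GT is converted to alt-allele dosage (0/1/2,
#' `./.` = missing). Multi-allelic records are kept but flagged
#' `biallelic = FALSE` for [filter_snps()]. An unsorted VCF is rejected.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records.")
  fmt <- v@gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF FORMAT must include GT for every record.")
  }
  pos <- as.integer(fix$POS)
  for (ch in unique(fix$CHROM)) {
    if (is.unsorted(pos[fix$CHROM == ch])) {
      abort(sprintf("VCF is unsorted within chromosome %s.", ch))
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt))
  dosage[alleles == "0/0"] <- 0
  dosage[alleles %in% c("0/1", "1/0")] <- 1
  dosage[alleles == "1/1"] <- 2
  # anything involving allele >= 2 (multi-allelic call) stays NA-dosage
  has_dp <- any(grepl("(^|:)DP(:|$)", fmt))
  depth <- if (has_dp) {
    d <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    d[is.na(d)] <- 0
    d
  } else {
    matrix(0, nrow(gt), ncol(gt))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0("snp_", fix$CHROM, "_", pos)[is.na(ids) | ids == "."]
  geno_matrix(
    tibble(
      chrom = fix$CHROM, pos = pos, id = ids, ref = fix$REF, alt = fix$ALT,
      biallelic = !grepl(",", fix$ALT, fixed = TRUE)
    ),
    dosage, depth, colnames(gt)
  )
}

#' Write genotypes as a minimal VCF v4.2 file
#'
#' @param g A [geno_matrix()].
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_mat"))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  gt_str <- matrix("./.", nrow(g$dosage), ncol(g$dosage))
  gt_str[!is.na(g$dosage) & g$dosage == 0] <- "0/0"
  gt_str[!is.na(g$dosage) & g$dosage == 1] <- "0/1"
  gt_str[!is.na(g$dosage) & g$dosage == 2] <- "1/1"
  cells <- matrix(
    paste0(gt_str, ":", round(g$depth)),
    nrow(g$dosage), ncol(g$dosage)
  )
  body <- apply(
    cbind(g$snps$chrom, g$snps$pos, g$snps$id, g$snps$ref, g$snps$alt,
          ".", "PASS", ".", "GT:DP", cells),
    1, paste, collapse = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write annotation tracks as BED files
#'
#' `read_annotations()` loads every `<track>.bed` in `dir` into a
#' [feature_annotation()]; `write_annotations()` writes one BED per
#' track. BED is 0-based half-open on disk and converted to the 1-based
#' closed internal convention on read (via `rtracklayer`).
#'
#' @param dir Directory of BED files.
#' @return A [feature_annotation()] (read) or invisibly the file paths
#'   (write).
#' @export
read_annotations <- function(dir) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("the rtracklayer package is required for BED input.")
  }
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no .bed files found in '%s'.", dir))
  tracks <- lapply(files, function(f) {
    gr <- rtracklayer::import(f, format = "BED")
    tr <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr)
    )
    st <- as.character(GenomicRanges::strand(gr))
    if (any(st != "*")) tr$strand <- st
    nm <- gr$name
    if (!is.null(nm)) tr$name <- nm
    tr
  })
  names(tracks) <- sub("\\.bed$", "", basename(files))
  feature_annotation(tracks)
}

#' @rdname read_annotations
#' @param ann A [feature_annotation()].
#' @export
write_annotations <- function(ann, dir) {
  stopifnot(inherits(ann, "feature_annotation"))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("the rtracklayer package is required for BED output.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(ann), ".bed"))
  for (i in seq_along(ann)) {
    gr <- .track_granges(ann[[i]])
    if ("name" %in% names(ann[[i]])) gr$name <- ann[[i]]$name
    gr$score <- 0
    rtracklayer::export(gr, paths[i], format = "BED")
  }
  invisible(paths)
}

#' Write an EWAS result table as TSV
#'
#' Fixed, documented column order: chrom, pos, beta, se, wald_z, p_value,
#' q_value, n_used, direction, converged, ratio_ref, ratio_contrast,
#' methdiff.
#'
#' @param results An `ewas_result` tibble from [run_ewas()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ewas_results <- function(results, path) {
  cols <- intersect(
    c("chrom", "pos", "beta", "se", "wald_z", "p_value", "q_value", "n_used",
      "direction", "converged", "ratio_ref", "ratio_contrast", "methdiff"),
    names(results)
  )
  readr::write_tsv(results[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write DMR calls as TSV and BED
#'
#' The TSV mirrors the standard region-table columns (coordinates, #DMC,
#' mean q, mean methylation difference, direction, distance to TSS and
#' gene when annotated); the BED companion is 0-based half-open.
#'
#' @param dmrs A `dmr_result` tibble from [call_dmrs()].
#' @param path Output TSV path; the BED is written alongside with
#'   extension `.bed`.
#' @return Invisibly, `path`.
#' @export
write_dmrs <- function(dmrs, path) {
  flat <- dmrs %>% select(-dplyr::any_of("members"))
  readr::write_tsv(flat, path, progress = FALSE)
  bed <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
    name = sprintf("DMR_%03d", seq_len(nrow(dmrs))), score = 0,
    strand = ifelse(dmrs$direction == "hyper", "+", "-")
  )
  readr::write_tsv(bed, sub("\\.tsv$", ".bed", path), col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Write a complete simulated study to disk
#'
#' Emits the exact formats the readers consume: per-sample Bismark
#' coverage files under `counts/`, `samples.tsv`, `genotypes.vcf` and BED
#' annotation tracks under `annotations/`.
#'
#' @param study A `sim_study` from [simulate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation_counts(study$methylation, file.path(dir, "counts"))
  write_sample_sheet(study$samples, file.path(dir, "samples.tsv"))
  write_genotypes_vcf(study$genotypes, file.path(dir, "genotypes.vcf"))
  write_annotations(study$annotation, file.path(dir, "annotations"))
  invisible(dir)
}
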