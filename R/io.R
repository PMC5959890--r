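#' Read and write GWAS summary statistics
#'
#' Tab-delimited summary statistics with one header line. The canonical
#' column set is SNP, CHR, BP, A1, A2, FREQ, BETA (or OR), SE, Z, P, N,
#' with DIRECTION where applicable; A1 is always the effect allele,
#' positions are 1-based, alleles upper-case. Internally the columns map
#' to the lower-case names used across the package (`snp_id`, `chr`,
#' `bp`, `a1`, `a2`, `freq_a1`, `beta`, `se`, `zstat`, `p`, `n`).
#' Unknown columns are preserved. Numbers round-trip losslessly (written
#' with 17 significant digits) and sub-normal p-values such as 3.5e-308
#' are parsed without underflow to zero.
#'
#' @param path File path.
#' @param required Internal column names that must be present (default:
#'   the linear-GWAS core set).
#' @param column_map Optional named character vector mapping file header
#'   names to internal names, for lenient reading of external dialects.
#' @return A data.frame in internal column naming.
#' @export
read_summary_stats <- function(path,
                               required = c("snp_id", "chr", "bp", "a1", "a2",
                                            "freq_a1", "beta", "se", "p"),
                               column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""), data.table = FALSE)
  map <- c(SNP = "snp_id", CHR = "chr", BP = "bp", A1 = "a1", A2 = "a2",
           FREQ = "freq_a1", BETA = "beta", SE = "se", Z = "zstat", P = "p",
           N = "n", OR = "or", LOG_OR = "log_or", SE_LOGOR = "se_log_or",
           L95 = "l95", U95 = "u95", DIRECTION = "direction",
           PREVALENCE = "prevalence")
  if (!is.null(column_map)) map <- c(column_map, map)
  hit <- names(dt) %in% names(map)
  names(dt)[hit] <- unname(map[names(dt)[hit]])
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if ("bp" %in% names(dt)) {
    bad <- which(!is.finite(dt$bp) | dt$bp <= 0 | dt$bp != round(dt$bp))
    if (length(bad))
      stop("malformed BP at data line ", bad[1L], call. = FALSE)
    dt$bp <- as.integer(dt$bp)
  }
  if ("freq_a1" %in% names(dt)) {
    bad <- which(!(dt$freq_a1 > 0 & dt$freq_a1 < 1))
    if (length(bad))
      stop("FREQ out of (0,1) at data line ", bad[1L], call. = FALSE)
  }
  for (al in intersect(c("a1", "a2"), names(dt))) dt[[al]] <- toupper(dt[[al]])
  dt
}

#' @rdname read_summary_stats
#' @param table Data.frame in internal naming.
#' @export
write_summary_stats <- function(table, path) {
  rev_map <- c(snp_id = "SNP", chr = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
               freq_a1 = "FREQ", beta = "BETA", se = "SE", zstat = "Z",
               p = "P", n = "N", or = "OR", log_or = "LOG_OR",
               se_log_or = "SE_LOGOR", l95 = "L95", u95 = "U95",
               direction = "DIRECTION", prevalence = "PREVALENCE",
               log_or_meta = "LOG_OR", se_meta = "SE_LOGOR", z_meta = "Z",
               p_meta = "P")
  out <- as.data.frame(table)
  hit <- names(out) %in% names(rev_map)
  names(out)[hit] <- unname(rev_map[names(out)[hit]])
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.17g", x)
    else as.character(x)
  }
  txt <- vapply(out, fmt, character(nrow(out)))
  if (nrow(out) == 1L) txt <- matrix(txt, nrow = 1L)
  lines <- c(paste(names(out), collapse = "\t"),
             apply(txt, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a dosage matrix with its variant map
#'
#' The dosage matrix is written as a plain tab-delimited matrix
#' (individuals x SNPs, header = SNP ids) with a sidecar variant map
#' (`<path>.variants.tsv`: SNP, CHR, BP, A1, A2, MAF; 1-based
#' positions).
#'
#' @param dosage Numeric matrix, individuals x SNPs.
#' @param variants Data.frame with `snp_id`, `chr`, `bp`, `a1`, `a2`,
#'   `maf`.
#' @param path Path of the dosage matrix file.
#' @return `write_dosage()` returns `path` invisibly; `read_dosage()`
#'   returns a list with `dosage` and `variants`.
#' @export
write_dosage <- function(dosage, variants, path) {
  stopifnot(ncol(dosage) == nrow(variants))
  data.table::fwrite(data.table::as.data.table(dosage), path, sep = "\t")
  vm <- data.frame(SNP = variants$snp_id, CHR = variants$chr,
                   BP = variants$bp, A1 = variants$a1, A2 = variants$a2,
                   MAF = sprintf("%.17g", variants$maf))
  data.table::fwrite(vm, paste0(path, ".variants.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  dosage <- as.matrix(data.table::fread(path, sep = "\t", data.table = FALSE))
  vm <- data.table::fread(paste0(path, ".variants.tsv"), sep = "\t",
                          data.table = FALSE)
  variants <- data.frame(snp_id = vm$SNP, chr = vm$CHR, bp = vm$BP,
                         a1 = vm$A1, a2 = vm$A2, maf = vm$MAF,
                         stringsAsFactors = FALSE)
  list(dosage = dosage, variants = variants)
}

#' Write a trio cohort to a directory of text files
#'
#' Serializes the phenotype-bearing parts of a cohort (dosages, variant
#' map, observed statuses, ages, covariates, truth, config) as TSV/YAML
#' so pipeline stages can run as separate processes.
#'
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage(cohort$offspring_dosage, cohort$variants,
               file.path(dir, "dosage.tsv"))
  ph <- data.frame(
    maternal_status = cohort$maternal_status,
    paternal_status = cohort$paternal_status,
    maternal_age = cohort$maternal_age,
    paternal_age = cohort$paternal_age
  )
  data.table::fwrite(ph, file.path(dir, "phenotypes.tsv"), sep = "\t")
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t")
  tr <- cohort$truth
  tr$log_or <- sprintf("%.17g", tr$log_or)
  data.table::fwrite(tr, file.path(dir, "truth.tsv"), sep = "\t")
  write_sim_config(cohort$config, file.path(dir, "config.yml"))
  alphas <- list(maternal_alpha = cohort$maternal_alpha,
                 paternal_alpha = cohort$paternal_alpha, seed = cohort$seed)
  yaml::write_yaml(alphas, file.path(dir, "model.yml"), precision = 15L)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  dm <- read_dosage(file.path(dir, "dosage.tsv"))
  ph <- data.table::fread(file.path(dir, "phenotypes.tsv"), sep = "\t",
                          data.table = FALSE)
  covs <- data.table::fread(file.path(dir, "covariates.tsv"), sep = "\t",
                            data.table = FALSE)
  for (cc in intersect(c("centre", "batch", "array"), names(covs)))
    covs[[cc]] <- factor(covs[[cc]])
  tr <- data.table::fread(file.path(dir, "truth.tsv"), sep = "\t",
                          data.table = FALSE)
  model <- yaml::read_yaml(file.path(dir, "model.yml"))
  cohort <- list(
    offspring_dosage = dm$dosage,
    variants = dm$variants,
    maternal_status = ph$maternal_status,
    paternal_status = ph$paternal_status,
    maternal_age = ph$maternal_age,
    paternal_age = ph$paternal_age,
    covariates = covs,
    truth = tr,
    config = read_sim_config(file.path(dir, "config.yml")),
    maternal_alpha = model$maternal_alpha,
    paternal_alpha = model$paternal_alpha,
    seed = model$seed
  )
  class(cohort) <- "trio_cohort"
  cohort
}

#' Read a BED-like gene annotation
#'
#' Tab-delimited columns chr, start, end, gene (header optional,
#' detected); coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @return Data.frame with `chr`, `start`, `end`, `gene`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("chr\tstart|^chr\t", tolower(first))
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          data.table = FALSE)
  if (ncol(dt) < 4L)
    stop("gene annotation needs 4 columns (chr, start, end, gene); line 1",
         call. = FALSE)
  names(dt)[1:4] <- c("chr", "start", "end", "gene")
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$end < dt$start)
  if (length(bad))
    stop("malformed gene annotation at data line ", bad[1L], call. = FALSE)
  dt[, 1:4]
}

#' Read / write GMT-style gene sets
#'
#' One set per line: set name, TAB, then tab-separated gene ids.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @return `read_gene_sets()` returns a named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-1L]),
                  vapply(parts, `[[`, character(1), 1L))
}

#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Export genotypes as a minimal VCF
#'
#' Writes hard-call genotypes (0/0, 0/1, 1/1 from dosages 0/1/2) as an
#' uncompressed VCFv4.2 file with A2 as REF and A1 (the effect allele)
#' as ALT.
#'
#' @param dosage Integer matrix, individuals x SNPs.
#' @param variants Variant map (`snp_id`, `chr`, `bp`, `a1`, `a2`).
#' @param path Output path.
#' @param sample_ids Optional sample names.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosage, variants, path,
                      sample_ids = sprintf("S%05d", seq_len(nrow(dosage)))) {
  stopifnot(ncol(dosage) == nrow(variants), all(dosage %in% 0:2))
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=proxygwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(j) {
    paste(c(variants$chr[j], variants$bp[j], variants$snp_id[j],
            variants$a2[j], variants$a1[j], ".", "PASS", ".", "GT",
            gt[dosage[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
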