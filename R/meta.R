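#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Combines per-study effects with weights `w_i = 1/se_i^2` (the
#' standard-error weighted scheme of METAL): combined effect
#' `sum(w b)/sum(w)`, standard error `1/sqrt(sum(w))`, two-sided normal
#' p-value. Effects must be on a common scale with alleles already
#' harmonized.
#'
#' @param effect Numeric vector of study effects (log odds ratios).
#' @param se Numeric vector of their standard errors (all > 0).
#' @return A one-row data.frame with `log_or`, `se`, `zstat`, `p`,
#'   `n_studies`.
#' @export
#' @examples
#' ivw_meta(c(0.2, 0.0), c(0.1, 0.05))
ivw_meta <- function(effect, se) {
  if (length(effect) == 0L) stop("no studies to combine", call. = FALSE)
  stopifnot(length(effect) == length(se))
  if (any(!is.finite(se) | se <= 0))
    stop("all standard errors must be positive and finite", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * effect) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  data.frame(log_or = b, se = s, zstat = z, p = 2 * stats::pnorm(-abs(z)),
             n_studies = length(effect))
}

#' Harmonize a study table to reference alleles
#'
#' Aligns each SNP's effect to the reference effect allele: records
#' matching (a1, a2) pass through; records with swapped alleles have
#' their effect sign flipped; anything else is dropped as unreconcilable.
#' Palindromic (A/T, C/G) SNPs cannot be checked for strand and pass
#' through with a warning.
#'
#' @param tab Study table with `snp_id`, `a1`, `a2` and an effect column.
#' @param ref Data.frame with reference `snp_id`, `a1`, `a2`.
#' @param effect_col Name of the effect column to sign-flip.
#' @return `tab` restricted to reconcilable SNPs, effects aligned to the
#'   reference alleles; attribute `n_unreconcilable` counts drops.
#' @export
harmonize_alleles <- function(tab, ref, effect_col = "log_or") {
  i <- match(tab$snp_id, ref$snp_id)
  known <- !is.na(i)
  ra1 <- toupper(ref$a1[i]); ra2 <- toupper(ref$a2[i])
  a1 <- toupper(tab$a1); a2 <- toupper(tab$a2)
  same <- known & a1 == ra1 & a2 == ra2
  swapped <- known & a1 == ra2 & a2 == ra1 & !same
  pal <- paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
  if (any(pal & (same | swapped)))
    warning(sum(pal & (same | swapped)),
            " palindromic SNP(s) harmonized without strand check")
  tab[[effect_col]][swapped] <- -tab[[effect_col]][swapped]
  tmp <- tab$a1[swapped]
  tab$a1[swapped] <- tab$a2[swapped]
  tab$a2[swapped] <- tmp
  if ("freq_a1" %in% names(tab))
    tab$freq_a1[swapped] <- 1 - tab$freq_a1[swapped]
  keep <- same | swapped
  out <- tab[keep, , drop = FALSE]
  attr(out, "n_unreconcilable") <- sum(known & !keep)
  out
}

#' Staged meta-analysis across proxy and case-control cohorts
#'
#' Reproduces the staged design used for family-history GWAS: the two
#' proxy cohorts (maternal, paternal) are combined first into a parental
#' meta-analysis; that result is then combined with the external
#' case-control study's stage 2 summary statistics where the SNP has
#' stage-2 results, and with stage 1 otherwise. The 4-character direction
#' string records, in the order (maternal, paternal, stage 1, stage 2),
#' the sign of each cohort's harmonized effect, with `?` for a cohort
#' that did not contribute at that SNP.
#'
#' @param maternal,paternal Case-control-scale tables ([transform_table()]
#'   output or any table with `snp_id`, `a1`, `a2`, `log_or`,
#'   `se_log_or`).
#' @param stage1,stage2 Optional external summary tables in the same
#'   layout; `NULL` for a proxy-only meta-analysis.
#' @return A data.frame of meta records: `snp_id`, `a1`, `a2`,
#'   `log_or_meta`, `se_meta`, `z_meta`, `p_meta`, `direction`,
#'   `n_cohorts`.
#' @export
staged_meta <- function(maternal, paternal, stage1 = NULL, stage2 = NULL) {
  cohorts <- list(maternal = maternal, paternal = paternal,
                  stage1 = stage1, stage2 = stage2)
  cohorts <- lapply(cohorts, function(x) {
    if (is.null(x)) return(NULL)
    stopifnot(all(c("snp_id", "a1", "a2", "log_or", "se_log_or") %in% names(x)))
    if ("flagged" %in% names(x)) x <- x[!x$flagged, , drop = FALSE]
    x[is.finite(x$log_or) & is.finite(x$se_log_or) & x$se_log_or > 0, ,
      drop = FALSE]
  })
  # reference alleles (and positions where known): first cohort carrying
  # each SNP
  ref <- NULL
  for (x in cohorts) {
    if (is.null(x)) next
    cols <- c("snp_id", "a1", "a2", intersect(c("chr", "bp"), names(x)))
    add <- x[!x$snp_id %in% ref$snp_id, cols, drop = FALSE]
    for (cc in setdiff(c("chr", "bp"), names(add)))
      add[[cc]] <- rep(NA, nrow(add))
    ref <- rbind(ref, add[, c("snp_id", "a1", "a2", "chr", "bp")])
  }
  cohorts <- lapply(cohorts, function(x)
    if (is.null(x)) NULL else harmonize_alleles(x, ref))

  snps <- ref$snp_id
  idx <- lapply(cohorts, function(x)
    if (is.null(x)) rep(NA_integer_, length(snps)) else match(snps, x$snp_id))
  eff <- lapply(names(cohorts), function(nm) {
    x <- cohorts[[nm]]; i <- idx[[nm]]
    if (is.null(x)) list(b = rep(NA_real_, length(snps)),
                         s = rep(NA_real_, length(snps)))
    else list(b = x$log_or[i], s = x$se_log_or[i])
  })
  names(eff) <- names(cohorts)

  out <- vector("list", length(snps))
  for (j in seq_along(snps)) {
    b <- vapply(eff, function(e) e$b[j], numeric(1))
    s <- vapply(eff, function(e) e$s[j], numeric(1))
    # stage 1 contributes only when stage 2 is absent at this SNP
    use <- c(!is.na(b[1]), !is.na(b[2]),
             !is.na(b[3]) && is.na(b[4]), !is.na(b[4]))
    if (!any(use)) next
    m <- ivw_meta(b[use], s[use])
    dir <- rep("?", 4L)
    dir[use] <- ifelse(b[use] >= 0, "+", "-")
    out[[j]] <- data.frame(
      snp_id = snps[j], a1 = ref$a1[j], a2 = ref$a2[j],
      log_or_meta = m$log_or, se_meta = m$se, z_meta = m$zstat,
      p_meta = m$p, direction = paste(dir, collapse = ""),
      n_cohorts = m$n_studies, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!all(is.na(ref$chr))) {
    i <- match(res$snp_id, ref$snp_id)
    res$chr <- ref$chr[i]
    res$bp <- ref$bp[i]
  }
  res
}

#' Sign concordance between two studies
#'
#' Counts SNPs whose effect signs agree between two harmonized tables,
#' over a supplied SNP list (default: all shared SNPs). Zero effects
#' count as concordant with either sign only if both are zero.
#'
#' @param tab_a,tab_b Tables with `snp_id`, `a1`, `a2` and an effect
#'   column (`log_or` by default; falls back to `log_or_meta`, `beta`).
#' @param snps Optional character vector restricting the comparison.
#' @return A list with `n_concordant`, `n_total`, `discordant` (snp ids).
#' @export
sign_concordance <- function(tab_a, tab_b, snps = NULL) {
  ecol <- function(x) intersect(c("log_or", "log_or_meta", "beta"), names(x))[1]
  ea <- ecol(tab_a); eb <- ecol(tab_b)
  if (is.na(ea) || is.na(eb)) stop("no effect column found", call. = FALSE)
  tab_b <- harmonize_alleles(tab_b, tab_a, effect_col = eb)
  shared <- intersect(tab_a$snp_id, tab_b$snp_id)
  if (!is.null(snps)) shared <- intersect(shared, snps)
  if (length(shared) == 0L) stop("no shared SNPs", call. = FALSE)
  a <- tab_a[[ea]][match(shared, tab_a$snp_id)]
  b <- tab_b[[eb]][match(shared, tab_b$snp_id)]
  conc <- sign(a) == sign(b)
  list(n_concordant = sum(conc), n_total = length(shared),
       discordant = shared[!conc])
}
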