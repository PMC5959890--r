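#' Overlapping-controls sensitivity analysis
#'
#' In a family-history design the maternal and paternal GWAS share
#' controls (the same genotyped offspring), so meta-analysing them could
#' in principle bias results. This check compares the combined 0/1/2
#' parental GWAS with the meta-analysis of the separate maternal and
#' paternal GWAS: it reports the Pearson correlation of per-SNP p-values
#' across shared SNPs (on the raw scale, and on -log10), and the
#' least-squares intercept and slope of one analysis's -log10 p on the
#' other's. Near-perfect correlation with intercept ~0 and slope ~1
#' indicates the overlap is innocuous.
#'
#' @param combined Table with per-SNP p-values (`p` or `p_meta`) from the
#'   combined 0/1/2 GWAS.
#' @param meta Table with per-SNP p-values from the maternal+paternal
#'   meta-analysis.
#' @return List: `n_shared`, `p_correlation`, `neglog_correlation`,
#'   `neglog_intercept`, `neglog_slope` (regression of the combined
#'   analysis's -log10 p on the meta-analysis's).
#' @export
overlap_sensitivity <- function(combined, meta) {
  pc <- get_pcol(combined); pm <- get_pcol(meta)
  shared <- intersect(combined$snp_id, meta$snp_id)
  if (length(shared) < 3L) stop("fewer than 3 shared SNPs", call. = FALSE)
  pa <- pc[match(shared, combined$snp_id)]
  pb <- pm[match(shared, meta$snp_id)]
  la <- -log10(pa); lb <- -log10(pb)
  fit <- stats::lm.fit(cbind(1, lb), la)
  list(
    n_shared = length(shared),
    p_correlation = stats::cor(pa, pb),
    neglog_correlation = stats::cor(la, lb),
    neglog_intercept = unname(fit$coefficients[1L]),
    neglog_slope = unname(fit$coefficients[2L])
  )
}

get_pcol <- function(tab) {
  col <- intersect(c("p", "p_meta", "p_gene"), names(tab))[1]
  if (is.na(col)) stop("no p-value column found", call. = FALSE)
  tab[[col]]
}

#' Genomic inflation factor
#'
#' Lambda is the median observed association chi-square divided by the
#' null median of a 1-df chi-square, `qchisq(0.5, 1)` (0.4549364...).
#' Values near 1 indicate bulk calibration; polygenic signal or
#' confounding inflate it.
#'
#' @param z Vector of z statistics, or `p` of two-sided p-values (one of
#'   the two must be given).
#' @param p Two-sided p-values (used when `z` is missing).
#' @return Lambda (scalar).
#' @export
genomic_inflation <- function(z = NULL, p = NULL) {
  if (is.null(z) && is.null(p)) stop("supply `z` or `p`", call. = FALSE)
  chisq <- if (!is.null(z)) z^2 else stats::qchisq(p, df = 1, lower.tail = FALSE)
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) == 0L) stop("no finite statistics", call. = FALSE)
  if (length(chisq) < 100L)
    warning("fewer than 100 tests: lambda is unstable")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Effect-size concordance between two analyses
#'
#' Pearson correlation of log odds ratios and the fraction of agreeing
#' effect signs across a SNP list (after allele harmonization), as used
#' to compare maternal against paternal proxy results and both against an
#' external case-control study.
#'
#' @param tab_a,tab_b Tables with `snp_id`, `a1`, `a2` and a log-OR
#'   column (`log_or`, `log_or_meta`, or `beta`).
#' @param snps Optional SNP subset.
#' @return List: `n_shared`, `r_log_or`, `sign_concordance`.
#' @export
effect_concordance <- function(tab_a, tab_b, snps = NULL) {
  ecol <- function(x) intersect(c("log_or", "log_or_meta", "beta"), names(x))[1]
  ea <- ecol(tab_a); eb <- ecol(tab_b)
  if (is.na(ea) || is.na(eb)) stop("no effect column found", call. = FALSE)
  tab_b <- harmonize_alleles(tab_b, tab_a, effect_col = eb)
  shared <- intersect(tab_a$snp_id, tab_b$snp_id)
  if (!is.null(snps)) shared <- intersect(shared, snps)
  if (length(shared) == 0L) stop("no shared SNPs", call. = FALSE)
  a <- tab_a[[ea]][match(shared, tab_a$snp_id)]
  b <- tab_b[[eb]][match(shared, tab_b$snp_id)]
  list(n_shared = length(shared),
       r_log_or = stats::cor(a, b),
       sign_concordance = mean(sign(a) == sign(b)))
}

#' Parameter-recovery report against simulation truth
#'
#' For each causal SNP, compares the estimated (rescaled) log odds ratio
#' from the final analysis table with the true allelic log odds ratio
#' implied by the generative model, and reports per-SNP 95% CI coverage
#' plus aggregate bias and RMSE. The unscaled proxy log-OR is reported
#' too: it should sit near half the true value, the empirical
#' justification for the two-fold rescaling.
#'
#' @param cohort A `trio_cohort` with truth.
#' @param table Case-control-scale table ([transform_table()] output)
#'   with `snp_id`, `log_or`, `se_log_or`; `or_unscaled` used if present.
#' @param true_or Optional named vector of true allelic ORs per causal
#'   snp_id (e.g. from [true_allelic_or()]); defaults to `exp(beta_j)`
#'   from the cohort truth.
#' @return List with `table` (per causal SNP: true and estimated log-OR,
#'   CI cover flag), `bias`, `rmse`, `coverage`, `mean_unscaled_ratio`
#'   (mean unscaled log-OR over true log-OR).
#' @export
recovery_report <- function(cohort, table, true_or = NULL) {
  truth <- cohort$truth
  if (is.null(truth)) stop("cohort carries no simulation truth", call. = FALSE)
  causal <- truth$snp_id[truth$causal]
  if (is.null(true_or))
    true_or <- stats::setNames(exp(truth$log_or[truth$causal]), causal)
  keep <- intersect(causal, table$snp_id)
  i <- match(keep, table$snp_id)
  est <- table$log_or[i]
  se <- table$se_log_or[i]
  tru <- log(true_or[keep])
  cover <- tru >= est - 1.959964 * se & tru <= est + 1.959964 * se
  unscaled <- if ("or_unscaled" %in% names(table)) log(table$or_unscaled[i])
              else est / 2
  out <- data.frame(snp_id = keep, true_log_or = unname(tru),
                    est_log_or = est, se = se, ci_covers = cover,
                    unscaled_log_or = unscaled, stringsAsFactors = FALSE)
  list(table = out,
       bias = mean(est - tru),
       rmse = sqrt(mean((est - tru)^2)),
       coverage = mean(cover),
       mean_unscaled_ratio = mean(unscaled / tru))
}
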