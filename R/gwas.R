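#' Residualize a phenotype on covariates
#'
#' Fits a least-squares regression of the (binary, possibly missing)
#' phenotype on the covariates and returns the residuals. Rows with a
#' missing phenotype are dropped from the fit and carry `NA` in the
#' result, so the output aligns with the input. Categorical covariates
#' are expanded to indicator columns via the standard model matrix.
#'
#' @param status Numeric/integer vector with `NA` for missing.
#' @param covariates Data.frame of covariates (may be `NULL` for an
#'   intercept-only fit, i.e. centering).
#' @return Numeric vector, same length as `status`, with residuals at
#'   analyzed rows and `NA` elsewhere. Attribute `n_dropped` counts the
#'   dropped rows.
#' @export
residualize <- function(status, covariates = NULL) {
  keep <- !is.na(status)
  if (!any(keep)) stop("no non-missing phenotype values", call. = FALSE)
  y <- as.numeric(status[keep])
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    if (anyNA(covariates))
      stop("covariates must be complete for analyzed rows", call. = FALSE)
    X <- stats::model.matrix(~ ., data = covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  res <- rep(NA_real_, length(status))
  res[keep] <- qr.resid(qrX, y)
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Per-SNP additive linear association
#'
#' Simple least-squares regression of the residualized phenotype on a SNP
#' dosage (additive coding 0/1/2), returning the slope, its standard
#' error, the z statistic and the two-sided p-value from the normal
#' approximation (the intended sample sizes make the t and normal
#' references indistinguishable).
#'
#' @param residuals Numeric vector (NAs allowed; those rows are dropped).
#' @param dosage Numeric vector of the same length.
#' @return A one-row data.frame with `beta`, `se`, `zstat`, `p`, `n`.
#' @export
snp_assoc <- function(residuals, dosage) {
  stopifnot(length(residuals) == length(dosage))
  keep <- !is.na(residuals) & !is.na(dosage)
  y <- residuals[keep]; x <- dosage[keep]
  out <- assoc_matrix(y, matrix(x, ncol = 1L))
  if (is.na(out$beta[1L]))
    stop("monomorphic SNP: dosage has zero variance", call. = FALSE)
  cbind(out, n = length(y))
}

# vectorized core: slope of y on each column of X (both complete),
# with intercept; returns beta/se/z/p per column, NA for zero-variance cols
assoc_matrix <- function(y, X) {
  n <- length(y)
  xbar <- colMeans(X)
  ybar <- mean(y)
  sxy <- as.numeric(crossprod(X, y)) - n * xbar * ybar
  sxx <- colSums(X^2) - n * xbar^2
  syy <- sum(y^2) - n * ybar^2
  ok <- sxx > .Machine$double.eps * n
  beta <- se <- z <- p <- rep(NA_real_, ncol(X))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - beta[ok] * sxy[ok], 0)
  se[ok] <- sqrt(rss / (n - 2L) / sxx[ok])
  zero_se <- se == 0 & !is.na(se)
  z[ok] <- ifelse(se[ok] > 0, beta[ok] / se[ok], 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[zero_se & beta == 0] <- 1
  data.frame(beta = beta, se = se, zstat = z, p = p)
}

#' Run a proxy-phenotype GWAS for one parent
#'
#' Residualizes the observed parental status (for rows where that parent's
#' status is non-missing) on parental age at death/report, assessment
#' centre, genotyping batch, array and the genetic principal components,
#' then regresses the residuals on each SNP dosage under the additive
#' model. SNPs failing the minor-allele-frequency filter (computed from
#' the analyzed sample) or, when imputation info scores are supplied, the
#' info filter, are omitted; monomorphic SNPs are dropped with a note in
#' the `dropped` attribute.
#'
#' @param cohort A `trio_cohort` with observed statuses.
#' @param parent `"maternal"` or `"paternal"`.
#' @param maf_min Minor allele frequency filter (exclusive), default 0.01.
#' @param info Optional per-SNP imputation quality scores.
#' @param info_min Info filter (exclusive), default 0.3, applied only when
#'   `info` is given.
#' @return A data.frame of association records (`snp_id`, `chr`, `bp`,
#'   `a1`, `a2`, `freq_a1`, `beta`, `se`, `zstat`, `p`, `n`) with
#'   attributes `prevalence` (case fraction of the analyzed set) and
#'   `n_analyzed`.
#' @export
run_proxy_gwas <- function(cohort, parent = c("maternal", "paternal"),
                           maf_min = 0.01, info = NULL, info_min = 0.3) {
  parent <- match.arg(parent)
  status <- cohort[[paste0(parent, "_status")]]
  if (is.null(status)) stop("cohort has no observed statuses", call. = FALSE)
  covs <- gwas_covariates(cohort, parent)
  keep <- !is.na(status) & stats::complete.cases(covs)
  if (sum(status[keep] == 1L) == 0L)
    stop("zero cases after exclusions: cannot run GWAS", call. = FALSE)
  res <- residualize(status[keep], covs[keep, , drop = FALSE])
  gwas_table(cohort, res, keep, maf_min, info, info_min,
             prevalence = mean(status[keep]))
}

#' Run a combined 0/1/2 parental GWAS
#'
#' Scores each offspring by the number of parents reported affected (0,
#' 1 or 2) over all rows where at least one parent's status is observed
#' (a parent excluded by the age rules contributes no case), and runs the
#' same residualized additive association machinery on that score. Used
#' by the overlapping-controls sensitivity analysis, which compares its
#' p-values with those of a meta-analysis of the separate maternal and
#' paternal GWAS; scoring over the union of the two analyzed samples
#' makes the two analyses use the same underlying data.
#'
#' A parental-age covariate that is missing for a row in the union (the
#' excluded parent's age) is mean-imputed so the row is retained.
#'
#' @inheritParams run_proxy_gwas
#' @return As [run_proxy_gwas()]; the `prevalence` attribute is the mean
#'   of the 0/1/2 score divided by 2.
#' @export
run_combined_gwas <- function(cohort, maf_min = 0.01, info = NULL,
                              info_min = 0.3) {
  sm <- cohort$maternal_status; sp <- cohort$paternal_status
  if (is.null(sm) || is.null(sp))
    stop("cohort has no observed statuses", call. = FALSE)
  score <- ifelse(is.na(sm), 0L, sm) + ifelse(is.na(sp), 0L, sp)
  covs <- gwas_covariates(cohort, "both")
  for (cc in intersect(c("maternal_age", "paternal_age"), names(covs))) {
    miss <- is.na(covs[[cc]])
    covs[[cc]][miss] <- mean(covs[[cc]][!miss])
  }
  keep <- (!is.na(sm) | !is.na(sp)) & stats::complete.cases(covs)
  if (!any(keep)) stop("no rows with an observed parental status",
                       call. = FALSE)
  if (stats::var(score[keep]) == 0)
    stop("degenerate combined phenotype: parental score is constant",
         call. = FALSE)
  res <- residualize(score[keep], covs[keep, , drop = FALSE])
  gwas_table(cohort, res, keep, maf_min, info, info_min,
             prevalence = mean(score[keep]) / 2)
}

gwas_covariates <- function(cohort, parent) {
  covs <- cohort$covariates
  if (is.null(covs)) return(NULL)
  age <- switch(parent,
    maternal = data.frame(parent_age = cohort$maternal_age),
    paternal = data.frame(parent_age = cohort$paternal_age),
    both = data.frame(maternal_age = cohort$maternal_age,
                      paternal_age = cohort$paternal_age))
  cbind(age, covs)
}

gwas_table <- function(cohort, res, keep, maf_min, info, info_min, prevalence) {
  X <- cohort$offspring_dosage[keep, , drop = FALSE]
  freq <- colMeans(X) / 2
  maf <- pmin(freq, 1 - freq)
  pass <- maf > maf_min
  if (!is.null(info)) {
    stopifnot(length(info) == ncol(X))
    pass <- pass & info > info_min
  }
  stats_cols <- assoc_matrix(as.numeric(res), X)
  mono <- is.na(stats_cols$beta)
  out <- cbind(cohort$variants[, c("snp_id", "chr", "bp", "a1", "a2")],
               freq_a1 = freq, stats_cols,
               n = nrow(X))
  dropped <- out$snp_id[!pass | mono]
  out <- out[pass & !mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prevalence") <- prevalence
  attr(out, "n_analyzed") <- sum(keep)
  attr(out, "dropped") <- dropped
  out
}
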