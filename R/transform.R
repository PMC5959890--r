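#' Convert a linear-model coefficient on a binary trait to an odds ratio
#'
#' For a binary disease with prevalence `k`, effect-allele frequency `p`
#' and a per-allele linear (probability-scale) regression coefficient
#' `beta`, the implied allele-level disease probabilities are
#' `P(D | A1) = k + beta (1 - p)` and `P(D | A2) = k - beta p`, and the
#' allelic odds ratio is their odds ratio:
#'
#' \deqn{OR = \frac{(k + \beta(1-p))(1 - k + \beta p)}
#'                 {(k - \beta p)(1 - k - \beta(1-p))}}
#'
#' All four factors must be strictly positive for the implied 2x2
#' allele-by-disease table to be valid.
#'
#' @param beta Linear regression coefficient(s) of disease on dosage.
#' @param p Effect-allele frequency in (0,1).
#' @param k Disease prevalence in (0,1).
#' @return The odds ratio (vectorized over the inputs).
#' @export
#' @examples
#' lmor(0.01, p = 0.5, k = 0.096)
lmor <- function(beta, p, k) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0,1)", call. = FALSE)
  if (any(k <= 0 | k >= 1)) stop("`k` must lie in (0,1)", call. = FALSE)
  t1 <- k + beta * (1 - p)
  t2 <- 1 - k + beta * p
  t3 <- k - beta * p
  t4 <- 1 - k - beta * (1 - p)
  terms <- cbind("k + beta(1-p)" = t1, "1 - k + beta p" = t2,
                 "k - beta p" = t3, "1 - k - beta(1-p)" = t4)
  bad <- terms <= 0
  if (any(bad)) {
    j <- which(colSums(bad) > 0)[1L]
    stop("odds-ratio conversion out of domain: term `",
         colnames(terms)[j], "` is non-positive", call. = FALSE)
  }
  (t1 * t2) / (t3 * t4)
}

#' Rescale a proxy odds ratio to the case-control scale
#'
#' A parent-offspring proxy design observes the effect through one meiosis,
#' halving the log-odds; the log-odds are therefore multiplied by two so
#' effect sizes are reported on the same scale as a traditional
#' case-control design. Equivalently the rescaled OR is the square of the
#' unscaled one.
#'
#' @param or_unscaled Odds ratio(s) from [lmor()]; must be positive.
#' @return The scaled log-odds, `2 * log(or_unscaled)`.
#' @export
proxy_scale <- function(or_unscaled) {
  if (any(!is.finite(or_unscaled) | or_unscaled <= 0))
    stop("odds ratio must be positive and finite", call. = FALSE)
  2 * log(or_unscaled)
}

#' Standard error of a log-odds from its p-value
#'
#' Recovers the standard error of a (rescaled) log-odds so that the z
#' statistic — and hence the p-value — of the original linear-model test
#' is preserved: `SE = |log OR| / z`, with `z` the upper-tail standard
#' normal quantile at `p/2`. The quantile is evaluated on the log scale so
#' p-values down to the smallest representable double do not underflow;
#' when `p` is degenerate (0, or the effect is exactly zero) the linear
#' model's own z statistic is used as a fallback, which is identical by
#' construction.
#'
#' @param log_or_scaled Scaled log-odds value(s).
#' @param p_value Two-sided p-value(s) from the linear GWAS.
#' @param fallback_z Optional z statistic(s) from the linear model.
#' @return Standard error(s) of the scaled log-odds.
#' @export
se_from_p <- function(log_or_scaled, p_value, fallback_z = NULL) {
  n <- max(length(log_or_scaled), length(p_value))
  log_or_scaled <- rep_len(log_or_scaled, n)
  p_value <- rep_len(p_value, n)
  z <- rep(NA_real_, n)
  ok <- !is.na(p_value) & p_value > 0 & p_value < 1
  z[ok] <- stats::qnorm(log(p_value[ok]) - log(2), lower.tail = FALSE,
                        log.p = TRUE)
  usable <- ok & is.finite(z) & z > 0 & log_or_scaled != 0
  if (!all(usable)) {
    if (is.null(fallback_z))
      stop("degenerate p-value and no fallback z statistic", call. = FALSE)
    fz <- abs(rep_len(fallback_z, n))
    if (any(!is.finite(fz[!usable]) | fz[!usable] == 0))
      stop("degenerate p-value and degenerate fallback z", call. = FALSE)
    z[!usable] <- fz[!usable]
  }
  abs(log_or_scaled) / z
}

#' Convert a linear GWAS table to the case-control scale
#'
#' Applies [lmor()], [proxy_scale()] and [se_from_p()] per SNP, using the
#' observed sample prevalence of the analyzed GWAS, and adds a 95%
#' confidence interval on the odds-ratio scale. SNPs for which the
#' conversion leaves its domain (extreme frequency-effect combinations)
#' are flagged rather than aborting the run, and carry `NA` effect
#' columns; flagged rows are excluded from downstream meta-analysis.
#'
#' @param assoc Association table from [run_proxy_gwas()] or
#'   [run_combined_gwas()] (columns `snp_id`, `a1`, `a2`, `freq_a1`,
#'   `beta`, `zstat`, `p` required).
#' @param k Disease prevalence of the analyzed GWAS; defaults to the
#'   table's `prevalence` attribute.
#' @return A data.frame of case-control records: `snp_id`, `a1`, `a2`,
#'   `freq_a1`, `prevalence`, `or_unscaled`, `log_or` (scaled),
#'   `se_log_or`, `zstat`, `p`, `n`, `or` (scaled OR), `l95`, `u95`,
#'   `direction` (`"+"`/`"-"`), `flagged`.
#' @export
transform_table <- function(assoc, k = attr(assoc, "prevalence")) {
  if (is.null(k)) stop("prevalence `k` must be supplied", call. = FALSE)
  stopifnot(all(c("snp_id", "a1", "a2", "freq_a1", "beta", "zstat", "p")
                %in% names(assoc)))
  n <- nrow(assoc)
  or_un <- rep(NA_real_, n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    or_un[i] <- tryCatch(lmor(assoc$beta[i], assoc$freq_a1[i], k),
                         error = function(e) NA_real_)
    flagged[i] <- is.na(or_un[i])
  }
  log_or <- se <- rep(NA_real_, n)
  ok <- !flagged
  log_or[ok] <- proxy_scale(or_un[ok])
  se[ok] <- se_from_p(log_or[ok], assoc$p[ok], fallback_z = assoc$zstat[ok])
  out <- data.frame(
    snp_id = assoc$snp_id, a1 = assoc$a1, a2 = assoc$a2,
    freq_a1 = assoc$freq_a1, prevalence = k,
    or_unscaled = or_un, log_or = log_or, se_log_or = se,
    zstat = assoc$zstat, p = assoc$p,
    n = if ("n" %in% names(assoc)) assoc$n else NA_integer_,
    or = exp(log_or),
    l95 = exp(log_or - 1.959964 * se),
    u95 = exp(log_or + 1.959964 * se),
    direction = ifelse(log_or >= 0, "+", "-"),
    flagged = flagged,
    stringsAsFactors = FALSE
  )
  if (any(c("chr", "bp") %in% names(assoc)))
    out <- cbind(out, assoc[, intersect(c("chr", "bp"), names(assoc)),
                            drop = FALSE])
  rownames(out) <- NULL
  if (any(flagged))
    warning(sum(flagged), " SNP(s) flagged: odds-ratio conversion out of domain")
  out
}
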