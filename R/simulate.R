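#' Simulate trio genotypes
#'
#' Draws per-SNP minor allele frequencies, parental genotypes in
#' Hardy-Weinberg equilibrium at those frequencies, and offspring dosages
#' by Mendelian transmission: each offspring inherits one allele drawn
#' uniformly from each parent's two alleles. This induces the classical
#' parent-offspring dosage correlation of 1/2 per SNP, the quantity that
#' motivates doubling proxy log-odds downstream.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"trio_cohort"` with integer matrices
#'   `offspring_dosage`, `maternal_genotype`, `paternal_genotype`
#'   (`n_offspring` x `n_snps`, values 0/1/2), a `variants` data.frame
#'   (snp_id, chr, bp, a1, a2, maf), and the `config`. Downstream steps
#'   ([simulate_parent_disease()], [apply_reporting_and_exclusions()])
#'   add disease truth, covariates and observed statuses.
#' @export
simulate_trio_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_offspring
  m <- config$n_snps

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pm <- rep(maf, each = n)

  gm <- matrix(stats::rbinom(n * m, 2L, pm), n, m)
  gf <- matrix(stats::rbinom(n * m, 2L, pm), n, m)
  # transmitted allele is Bernoulli(g/2) given parental dosage g
  tm <- matrix(stats::rbinom(n * m, 1L, gm / 2), n, m)
  tf <- matrix(stats::rbinom(n * m, 1L, gf / 2), n, m)
  child <- tm + tf
  storage.mode(gm) <- "integer"
  storage.mode(gf) <- "integer"
  storage.mode(child) <- "integer"

  # one synthetic chromosome, SNPs spaced ~10 kb apart
  bp <- cumsum(sample(5000:15000, m, replace = TRUE))
  variants <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chr = 1L,
    bp = as.integer(bp),
    a1 = "A",
    a2 = "G",
    maf = maf,
    stringsAsFactors = FALSE
  )
  colnames(child) <- colnames(gm) <- colnames(gf) <- variants$snp_id

  cohort <- list(
    offspring_dosage = child,
    maternal_genotype = gm,
    paternal_genotype = gf,
    variants = variants,
    config = config,
    seed = config$seed
  )
  class(cohort) <- "trio_cohort"
  cohort
}

#' Simulate parental disease status
#'
#' Assigns true disease status to one parent per trio under a logistic
#' model on that parent's own genotype,
#' `P(D = 1 | g) = plogis(alpha + sum_j beta_j g_j)`, where the causal
#' effects `beta_j` come from the configuration and the intercept `alpha`
#' is calibrated by bisection so that the population-average risk over the
#' simulated parental genotype distribution equals the configured
#' prevalence (maternal or paternal) to within 1e-6.
#'
#' @param cohort A `trio_cohort` from [simulate_trio_genotypes()].
#' @param parent `"maternal"` or `"paternal"`.
#' @return The cohort with added elements `<parent>_disease` (0/1 vector),
#'   `truth` (per-SNP true log-odds, shared across parents) and
#'   `<parent>_alpha` (calibrated intercept).
#' @export
simulate_parent_disease <- function(cohort, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  config <- cohort$config
  set.seed(config$seed + if (parent == "maternal") 1L else 2L)

  if (is.null(cohort$truth)) {
    beta <- numeric(config$n_snps)
    if (config$n_causal > 0L) {
      idx <- sample.int(config$n_snps, config$n_causal)
      beta[idx] <- rep_len(config$causal_log_or, config$n_causal)
    }
    cohort$truth <- data.frame(
      snp_id = cohort$variants$snp_id,
      log_or = beta,
      causal = beta != 0,
      stringsAsFactors = FALSE
    )
  }
  beta <- cohort$truth$log_or
  g <- if (parent == "maternal") cohort$maternal_genotype else cohort$paternal_genotype
  eta <- if (any(beta != 0)) drop(g %*% beta) else numeric(nrow(g))
  k <- if (parent == "maternal") config$k_maternal else config$k_paternal

  alpha <- calibrate_intercept(eta, k)
  prob <- stats::plogis(alpha + eta)
  status <- stats::rbinom(length(prob), 1L, prob)

  cohort[[paste0(parent, "_disease")]] <- status
  cohort[[paste0(parent, "_alpha")]] <- alpha
  cohort
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Bisection on `mean(plogis(alpha + eta)) - k` over the linear-predictor
#' distribution `eta`; converges because the mean risk is strictly
#' increasing in `alpha`.
#'
#' @param eta Numeric vector of genetic linear predictors.
#' @param k Target prevalence in (0,1).
#' @param tol Tolerance on the prevalence scale.
#' @return The intercept `alpha`.
#' @keywords internal
calibrate_intercept <- function(eta, k, tol = 1e-6) {
  stopifnot(k > 0, k < 1)
  f <- function(a) mean(stats::plogis(a + eta)) - k
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "prevalence calibration failed to bracket k = %g (mean risk at alpha = %g is %g, at %g is %g)",
      k, lo, f(lo) + k, hi, f(hi) + k), call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate parental ages and offspring covariates
#'
#' Draws parental age at death or at the offspring's report, flags for
#' death before age 60 and for missing age, and offspring-level nuisance
#' covariates (assessment centre, genotyping batch, array, genetic PCs).
#'
#' @param cohort A `trio_cohort`.
#' @return The cohort with `maternal_age`, `paternal_age` (NA when
#'   missing), `maternal_dead_before_60`, `paternal_dead_before_60`
#'   logical vectors, and a `covariates` data.frame.
#' @export
simulate_ages_and_covariates <- function(cohort) {
  config <- cohort$config
  set.seed(config$seed + 3L)
  n <- config$n_offspring

  draw_age <- function() {
    age <- stats::rnorm(n, config$parent_age_mean, config$parent_age_sd)
    dead60 <- stats::runif(n) < config$p_dead_before_60
    age[dead60] <- stats::runif(sum(dead60), 40, 60)
    miss <- stats::runif(n) < config$p_missing_age
    age[miss] <- NA_real_
    list(age = age, dead60 = dead60)
  }
  am <- draw_age()
  af <- draw_age()

  cov <- data.frame(
    centre = factor(sample.int(config$n_centres, n, replace = TRUE)),
    batch = factor(sample.int(config$n_batches, n, replace = TRUE)),
    array = factor(sample.int(2L, n, replace = TRUE))
  )
  if (config$n_pcs > 0L) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
    colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
    cov <- cbind(cov, as.data.frame(pcs))
  }

  cohort$maternal_age <- am$age
  cohort$paternal_age <- af$age
  cohort$maternal_dead_before_60 <- am$dead60
  cohort$paternal_dead_before_60 <- af$dead60
  cohort$covariates <- cov
  cohort
}

#' Apply informant-report misclassification and age exclusions
#'
#' Converts true parental disease into the observed (reported) status.
#' True status is flipped according to the configured report sensitivity
#' and specificity, independently per parent; an optional covariate effect
#' (first PC) shifts the reporting probability on the log-odds scale to
#' emulate ascertainment artifacts. The observed status is then set to
#' missing (NA) whenever an exclusion rule fires: parent aged under 60,
#' parent dead before age 60, or parental age missing.
#'
#' @param cohort A `trio_cohort` with disease, ages and covariates.
#' @return The cohort with `maternal_status`, `paternal_status` (0/1/NA)
#'   and an `exclusions` data.frame counting each rule's firings per
#'   parent.
#' @export
apply_reporting_and_exclusions <- function(cohort) {
  config <- cohort$config
  set.seed(config$seed + 4L)
  excl <- list()
  for (parent in c("maternal", "paternal")) {
    true <- cohort[[paste0(parent, "_disease")]]
    if (is.null(true))
      stop("simulate_parent_disease() must run before reporting", call. = FALSE)
    age <- cohort[[paste0(parent, "_age")]]
    dead60 <- cohort[[paste0(parent, "_dead_before_60")]]

    shift <- 0
    if (config$covariate_report_effect != 0 && !is.null(cohort$covariates$PC1))
      shift <- config$covariate_report_effect * cohort$covariates$PC1
    p_report <- ifelse(
      true == 1L,
      stats::plogis(stats::qlogis(clamp01(config$report_sensitivity)) + shift),
      stats::plogis(stats::qlogis(clamp01(1 - config$report_specificity)) + shift)
    )
    observed <- stats::rbinom(length(true), 1L, p_report)

    young <- !is.na(age) & age < 60 & !dead60
    missing_age <- is.na(age)
    drop <- young | dead60 | missing_age
    observed[drop] <- NA_integer_

    cohort[[paste0(parent, "_status")]] <- observed
    excl[[parent]] <- data.frame(
      parent = parent,
      aged_under_60 = sum(young),
      dead_before_60 = sum(dead60),
      missing_age = sum(missing_age),
      excluded = sum(drop),
      stringsAsFactors = FALSE
    )
  }
  cohort$exclusions <- do.call(rbind, excl)
  rownames(cohort$exclusions) <- NULL
  if (all(is.na(cohort$maternal_status)) && all(is.na(cohort$paternal_status)))
    warning("all observed statuses are missing after exclusions")
  cohort
}

# qlogis(0) / qlogis(1) are infinite; keep reporting probabilities in (0,1)
# representable when a covariate shift is added
clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Simulate a complete trio cohort
#'
#' Convenience wrapper running [simulate_trio_genotypes()],
#' [simulate_parent_disease()] for both parents,
#' [simulate_ages_and_covariates()] and
#' [apply_reporting_and_exclusions()] in order.
#'
#' @param config A [sim_config()] object.
#' @return A fully populated `trio_cohort`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_offspring = 200, n_snps = 20,
#'                                      n_causal = 2, seed = 7))
#' mean(cohort$maternal_status, na.rm = TRUE)
simulate_cohort <- function(config) {
  cohort <- simulate_trio_genotypes(config)
  cohort <- simulate_parent_disease(cohort, "maternal")
  cohort <- simulate_parent_disease(cohort, "paternal")
  cohort <- simulate_ages_and_covariates(cohort)
  apply_reporting_and_exclusions(cohort)
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d offspring x %d SNPs (%d causal), seed %d\n",
              x$config$n_offspring, x$config$n_snps,
              sum(x$truth$causal %||% FALSE), x$seed))
  for (parent in c("maternal", "paternal")) {
    st <- x[[paste0(parent, "_status")]]
    if (!is.null(st))
      cat(sprintf("  %s: %d cases / %d observed (prevalence %.4f)\n", parent,
                  sum(st == 1L, na.rm = TRUE), sum(!is.na(st)),
                  mean(st, na.rm = TRUE)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth allelic odds ratio at a SNP
#'
#' Computes the allele-level odds ratio of parental disease implied by the
#' generative model, by tabulating the expected allele-by-disease 2x2
#' table over a large freshly simulated parent population: each parent
#' contributes two allele copies, and disease counts are accrued as
#' expected counts under the logistic risk (so Monte Carlo error comes
#' only from the genotype draw). This marginal odds ratio is the target
#' the rescaled proxy estimate should recover; with independent causal
#' SNPs and small effects it is close to `exp(beta_j)`.
#'
#' With few causal SNPs (`<= 12` besides the target) the expectation over
#' the companion allele and the other causal genotypes is instead
#' enumerated exactly under Hardy-Weinberg, removing Monte Carlo error
#' entirely (`method = "exact"`, the default when feasible).
#'
#' @param cohort A `trio_cohort` with disease truth.
#' @param snp Index or snp_id of the SNP.
#' @param parent Which parent's calibrated model to use.
#' @param n_pop Size of the simulated parent population.
#' @param method `"exact"` enumeration or `"simulation"` tabulation;
#'   `"auto"` picks exact when at most 12 other causal SNPs exist.
#' @return The allelic odds ratio, or `NA` with a warning for a
#'   monomorphic SNP.
#' @export
true_allelic_or <- function(cohort, snp, parent = c("maternal", "paternal"),
                            n_pop = 200000L,
                            method = c("auto", "exact", "simulation")) {
  parent <- match.arg(parent)
  method <- match.arg(method)
  if (is.character(snp)) snp <- match(snp, cohort$variants$snp_id)
  if (is.na(snp) || snp < 1L || snp > nrow(cohort$variants))
    stop("SNP index out of range", call. = FALSE)
  alpha <- cohort[[paste0(parent, "_alpha")]]
  if (is.null(alpha))
    stop("simulate_parent_disease() must run before true_allelic_or()",
         call. = FALSE)
  beta <- cohort$truth$log_or
  maf <- cohort$variants$maf
  if (maf[snp] <= 0 || maf[snp] >= 1) {
    warning("monomorphic SNP: allelic odds ratio undefined")
    return(NA_real_)
  }

  causal <- which(beta != 0)
  others <- setdiff(causal, snp)
  if (method == "auto")
    method <- if (length(others) <= 12L) "exact" else "simulation"

  if (method == "exact") {
    # P(D | one allele copy a at snp): companion allele ~ Bern(maf),
    # other causal genotypes ~ HWE, all independent
    p_disease_given_allele <- function(a) {
      eta <- beta[snp] * a
      # expectation via convolution over independent genotype terms
      terms <- list(list(v = beta[snp] * c(0, 1),
                         w = c(1 - maf[snp], maf[snp])))
      for (j in others) {
        q <- maf[j]
        terms[[length(terms) + 1L]] <-
          list(v = beta[j] * (0:2), w = c((1 - q)^2, 2 * q * (1 - q), q^2))
      }
      grid <- data.frame(v = 0, w = 1)
      for (t in terms) {
        grid <- data.frame(v = rep(grid$v, each = length(t$v)) +
                             rep(t$v, times = nrow(grid)),
                           w = rep(grid$w, each = length(t$w)) *
                             rep(t$w, times = nrow(grid)))
      }
      sum(grid$w * stats::plogis(alpha + eta + grid$v))
    }
    p1 <- p_disease_given_allele(1)
    p0 <- p_disease_given_allele(0)
    return((p1 / (1 - p1)) / (p0 / (1 - p0)))
  }

  eta_other <- numeric(n_pop)
  for (j in others)
    eta_other <- eta_other + beta[j] * stats::rbinom(n_pop, 2L, maf[j])
  g <- stats::rbinom(n_pop, 2L, maf[snp])
  risk <- stats::plogis(alpha + eta_other + beta[snp] * g)

  # allele copies: genotype g contributes g copies of A1 and (2-g) of A2
  case_a1 <- sum(g * risk);       ctrl_a1 <- sum(g * (1 - risk))
  case_a2 <- sum((2 - g) * risk); ctrl_a2 <- sum((2 - g) * (1 - risk))
  if (case_a1 + ctrl_a1 == 0 || case_a2 + ctrl_a2 == 0) {
    warning("no allele copies observed: allelic odds ratio undefined")
    return(NA_real_)
  }
  (case_a1 * ctrl_a2) / (ctrl_a1 * case_a2)
}
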