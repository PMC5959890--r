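#' Simulation configuration for a trio cohort
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and its component steps. The defaults describe a
#' UK-Biobank-like parental-history design: maternal disease prevalence
#' 0.096, paternal 0.055 (a 1.7-fold difference driven by sex differences
#' in longevity), offspring genotyped at independent autosomal SNPs, and
#' parental status observed only through informant report with imperfect
#' sensitivity/specificity and age-based exclusions.
#'
#' @param n_offspring Number of genotyped offspring (one trio each).
#' @param n_snps Number of simulated biallelic SNPs.
#' @param maf_range Length-2 numeric, lower/upper bound of the uniform
#'   distribution from which per-SNP minor allele frequencies are drawn.
#'   Must lie within (0.01, 0.5].
#' @param n_causal Number of SNPs with a nonzero effect on parental
#'   disease liability; the causal set is drawn at random.
#' @param causal_log_or Per-allele log-odds effect of each causal SNP on
#'   parental disease. Scalar (recycled) or vector of length `n_causal`.
#' @param k_maternal,k_paternal Target population prevalences of the
#'   disease in mothers and fathers; the logistic intercept is calibrated
#'   so the simulated prevalence matches these.
#' @param report_sensitivity Probability that a truly affected parent is
#'   reported affected by the offspring.
#' @param report_specificity Probability that a truly unaffected parent is
#'   reported unaffected.
#' @param parent_age_mean,parent_age_sd Mean/SD (years) of parental age at
#'   death or at the offspring's report.
#' @param p_dead_before_60 Probability a parent died before age 60
#'   (excluded from analysis).
#' @param p_missing_age Probability the parental age is missing (excluded).
#' @param n_centres,n_batches,n_pcs Numbers of assessment centres,
#'   genotyping batches and genetic principal components simulated as
#'   covariates. Two genotyping arrays are always simulated.
#' @param covariate_report_effect Log-odds effect of a one-unit covariate
#'   shift on the reporting probability (ascertainment artifact); default 0
#'   so covariates are pure noise.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_offspring = 500, n_snps = 50, seed = 1)
sim_config <- function(n_offspring = 20000,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       n_causal = 50,
                       causal_log_or = 0.18,
                       k_maternal = 0.096,
                       k_paternal = 0.055,
                       report_sensitivity = 0.85,
                       report_specificity = 0.99,
                       parent_age_mean = 75,
                       parent_age_sd = 8,
                       p_dead_before_60 = 0.05,
                       p_missing_age = 0.02,
                       n_centres = 5,
                       n_batches = 4,
                       n_pcs = 10,
                       covariate_report_effect = 0,
                       seed = 1L) {
  cfg <- list(
    n_offspring = as.integer(n_offspring),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    n_causal = as.integer(n_causal),
    causal_log_or = as.numeric(causal_log_or),
    k_maternal = k_maternal,
    k_paternal = k_paternal,
    report_sensitivity = report_sensitivity,
    report_specificity = report_specificity,
    parent_age_mean = parent_age_mean,
    parent_age_sd = parent_age_sd,
    p_dead_before_60 = p_dead_before_60,
    p_missing_age = p_missing_age,
    n_centres = as.integer(n_centres),
    n_batches = as.integer(n_batches),
    n_pcs = as.integer(n_pcs),
    covariate_report_effect = covariate_report_effect,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_offspring < 1L) stop("`n_offspring` must be at least 1", call. = FALSE)
  if (cfg$n_snps < 1L) stop("`n_snps` must be at least 1", call. = FALSE)
  if (length(cfg$maf_range) != 2L || any(!is.finite(cfg$maf_range)))
    stop("`maf_range` must be two finite numbers", call. = FALSE)
  if (cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0.01 || cfg$maf_range[2] > 0.5)
    stop("`maf_range` must be an increasing pair within (0.01, 0.5]",
         call. = FALSE)
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_snps)
    stop("`n_causal` must be between 0 and `n_snps`", call. = FALSE)
  if (!(length(cfg$causal_log_or) %in% c(1L, max(1L, cfg$n_causal))))
    stop("`causal_log_or` must be scalar or length `n_causal`", call. = FALSE)
  for (nm in c("k_maternal", "k_paternal")) {
    k <- cfg[[nm]]
    if (!is.numeric(k) || k <= 0 || k >= 1)
      stop(sprintf("`%s` must be a prevalence in (0,1)", nm), call. = FALSE)
  }
  if (cfg$k_paternal > cfg$k_maternal)
    stop("`k_paternal` must not exceed `k_maternal`", call. = FALSE)
  for (nm in c("report_sensitivity", "report_specificity",
               "p_dead_before_60", "p_missing_age")) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || p < 0 || p > 1)
      stop(sprintf("`%s` must be a probability in [0,1]", nm), call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @param cfg A `sim_config` object.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}
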