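test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(maf_range = c(0.005, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(n_causal = 100, n_snps = 50), "n_causal")
  expect_error(sim_config(k_maternal = 0.05, k_paternal = 0.1), "k_paternal")
  expect_error(sim_config(report_sensitivity = 1.2), "report_sensitivity")
  expect_s3_class(sim_config(n_offspring = 10, n_snps = 2, n_causal = 0),
                  "sim_config")
})

test_that("Mendelian transmission forces offspring dosage from parents", {
  co <- simulate_trio_genotypes(tiny_config(n_offspring = 2000, n_snps = 20))
  both0 <- co$maternal_genotype == 0L & co$paternal_genotype == 0L
  expect_true(all(co$offspring_dosage[both0] == 0L))
  both2 <- co$maternal_genotype == 2L & co$paternal_genotype == 2L
  expect_true(all(co$offspring_dosage[both2] == 2L))
  # child allele counts bounded by transmissible alleles
  expect_true(all(co$offspring_dosage <=
                  co$maternal_genotype / 2 + co$paternal_genotype / 2 + 1))
})

test_that("parent-offspring dosage correlation converges to 1/2", {
  n <- 50000
  co <- simulate_trio_genotypes(
    sim_config(n_offspring = n, n_snps = 4, maf_range = c(0.45, 0.5),
               n_causal = 0, seed = 11))
  for (j in 1:4) {
    r <- cor(co$offspring_dosage[, j], co$maternal_genotype[, j])
    expect_lt(abs(r - 0.5), 3 / sqrt(n) + 0.006)
    r2 <- cor(co$offspring_dosage[, j], co$paternal_genotype[, j])
    expect_lt(abs(r2 - 0.5), 3 / sqrt(n) + 0.006)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_cohort(tiny_config(seed = 77))
  b <- simulate_cohort(tiny_config(seed = 77))
  expect_identical(a$offspring_dosage, b$offspring_dosage)
  expect_identical(a$maternal_status, b$maternal_status)
  expect_identical(a$exclusions, b$exclusions)
  c_ <- simulate_cohort(tiny_config(seed = 78))
  expect_false(identical(a$offspring_dosage, c_$offspring_dosage))
})

test_that("intercept calibration hits the target prevalence", {
  # intercept-only model: prevalence equals k up to binomial error
  cfg <- sim_config(n_offspring = 20000, n_snps = 5, n_causal = 0,
                    k_maternal = 0.096, k_paternal = 0.055, seed = 3)
  co <- simulate_trio_genotypes(cfg)
  co <- simulate_parent_disease(co, "maternal")
  co <- simulate_parent_disease(co, "paternal")
  km <- mean(co$maternal_disease); kp <- mean(co$paternal_disease)
  expect_lt(abs(km - 0.096), 3 * sqrt(0.096 * 0.904 / 20000))
  expect_lt(abs(kp - 0.055), 3 * sqrt(0.055 * 0.945 / 20000))
  expect_equal(km / kp, 1.7, tolerance = 0.12)
  expect_lt(abs(plogis(co$maternal_alpha) - 0.096), 1.1e-6)
})

test_that("calibration holds with genetic effects present", {
  cfg <- tiny_config(n_offspring = 30000, n_snps = 30, n_causal = 10,
                     causal_log_or = 0.3, seed = 9)
  co <- simulate_trio_genotypes(cfg)
  co <- simulate_parent_disease(co, "maternal")
  expect_lt(abs(mean(co$maternal_disease) - 0.096),
            3 * sqrt(0.096 * 0.904 / 30000))
})

test_that("reporting flips statuses at the configured rates", {
  cfg <- ideal_config(n_offspring = 20000, n_snps = 5, n_causal = 0,
                      report_sensitivity = 0.8, report_specificity = 0.95,
                      seed = 21)
  co <- simulate_cohort(cfg)
  true <- co$maternal_disease
  obs <- co$maternal_status
  sens <- mean(obs[true == 1L] == 1L)
  spec <- mean(obs[true == 0L] == 0L)
  n1 <- sum(true == 1L); n0 <- sum(true == 0L)
  expect_lt(abs(sens - 0.8), 3 * sqrt(0.8 * 0.2 / n1))
  expect_lt(abs(spec - 0.95), 3 * sqrt(0.95 * 0.05 / n0))
})

test_that("perfect reporting with no exclusions reproduces true status", {
  co <- simulate_cohort(ideal_config(seed = 31))
  expect_identical(as.integer(co$maternal_status),
                   as.integer(co$maternal_disease))
  expect_identical(as.integer(co$paternal_status),
                   as.integer(co$paternal_disease))
  expect_true(all(co$exclusions$excluded == 0L))
})

test_that("age exclusion rules set statuses to missing", {
  # all parents under 60 -> everything missing, with a warning
  cfg <- tiny_config(n_offspring = 300, n_snps = 5, n_causal = 0,
                     parent_age_mean = 50, parent_age_sd = 1,
                     p_dead_before_60 = 0, p_missing_age = 0, seed = 41)
  expect_warning(co <- simulate_cohort(cfg), "missing")
  expect_true(all(is.na(co$maternal_status)))
  expect_true(all(is.na(co$paternal_status)))
  expect_equal(co$exclusions$aged_under_60,
               c(300L, 300L))
})

test_that("true allelic OR oracle recovers the generative effect", {
  cfg <- ideal_config(n_offspring = 500, n_snps = 20, n_causal = 2,
                      causal_log_or = log(1.2), seed = 51)
  co <- simulate_cohort(cfg)
  jc <- which(co$truth$causal)[1]
  jn <- which(!co$truth$causal)[1]
  # null SNP: exactly 1 under exact enumeration
  expect_equal(true_allelic_or(co, jn), 1.0, tolerance = 1e-12)
  # causal SNP: close to exp(beta) (small non-collapsibility attenuation)
  expect_equal(true_allelic_or(co, jc), 1.2, tolerance = 0.005)
  # simulation tabulation agrees with exact enumeration
  set.seed(1)
  expect_equal(true_allelic_or(co, jc, method = "simulation",
                               n_pop = 400000L),
               true_allelic_or(co, jc), tolerance = 0.01)
  expect_error(true_allelic_or(co, 10000), "out of range")
})
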