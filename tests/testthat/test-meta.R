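test_that("ivw_meta identities: single study, symmetry, hand example", {
  one <- ivw_meta(0.13, 0.04)
  expect_equal(one$log_or, 0.13)
  expect_equal(one$se, 0.04)
  # two identical studies halve the variance
  two <- ivw_meta(c(0.1, 0.1), c(0.05, 0.05))
  expect_equal(two$log_or, 0.1)
  expect_equal(two$se, 0.05 / sqrt(2), tolerance = 1e-12)
  # hand-computed: w = (100, 400); effect = 100*0.2/500; se = 1/sqrt(500)
  hand <- ivw_meta(c(0.2, 0.0), c(0.1, 0.05))
  expect_equal(hand$log_or, 0.04, tolerance = 1e-12)
  expect_equal(hand$se, 1 / sqrt(500), tolerance = 1e-12)
  expect_equal(hand$se, 0.044721, tolerance = 1e-5)
  expect_error(ivw_meta(numeric(0), numeric(0)), "no studies")
  expect_error(ivw_meta(0.1, -0.1), "positive")
})

test_that("meta variance never exceeds any input variance", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    se <- runif(k, 0.01, 0.5)
    m <- ivw_meta(rnorm(k), se)
    expect_lt(m$se, min(se) + 1e-15)
  }
})

test_that("IVW combination is associative: staged equals one-step", {
  set.seed(33)
  b <- rnorm(4); s <- runif(4, 0.02, 0.2)
  onestep <- ivw_meta(b, s)
  ab <- ivw_meta(b[1:2], s[1:2])
  cd <- ivw_meta(b[3:4], s[3:4])
  twostep <- ivw_meta(c(ab$log_or, cd$log_or), c(ab$se, cd$se))
  expect_equal(twostep$log_or, onestep$log_or, tolerance = 1e-12)
  expect_equal(twostep$se, onestep$se, tolerance = 1e-12)
})

cc_table <- function(snp_id, log_or, se, a1 = "A", a2 = "G") {
  data.frame(snp_id = snp_id, a1 = a1, a2 = a2, log_or = log_or,
             se_log_or = se, stringsAsFactors = FALSE)
}

test_that("staged_meta builds direction strings per the staged design", {
  mat <- cc_table(c("rs1", "rs2", "rs3"), c(0.2, 0.1, 0.3), 0.05)
  pat <- cc_table(c("rs1", "rs2", "rs3"), c(0.1, 0.2, 0.1), 0.06)
  s1 <- cc_table(c("rs1", "rs2"), c(0.15, -0.05), 0.04)
  s2 <- cc_table("rs1", 0.12, 0.03)
  out <- staged_meta(mat, pat, s1, s2)
  # rs1: stage 2 present -> stage 1 shows '?'
  expect_equal(out$direction[out$snp_id == "rs1"], "++?+")
  expect_equal(out$n_cohorts[out$snp_id == "rs1"], 3L)
  # rs2: no stage 2 -> stage 1 contributes, slot 4 is '?'
  expect_equal(out$direction[out$snp_id == "rs2"], "++-?")
  # rs3: proxy-only SNP
  expect_equal(out$direction[out$snp_id == "rs3"], "++??")
  # combined effect for rs1 equals the explicit three-study IVW
  manual <- ivw_meta(c(0.2, 0.1, 0.12), c(0.05, 0.06, 0.03))
  expect_equal(out$log_or_meta[out$snp_id == "rs1"], manual$log_or,
               tolerance = 1e-12)
})

test_that("staged proxy-then-external grouping equals one-step IVW per SNP", {
  set.seed(14)
  n <- 30
  ids <- paste0("rs", 1:n)
  mat <- cc_table(ids, rnorm(n, 0, 0.1), runif(n, 0.02, 0.1))
  pat <- cc_table(ids, rnorm(n, 0, 0.1), runif(n, 0.02, 0.1))
  s2 <- cc_table(ids, rnorm(n, 0, 0.1), runif(n, 0.02, 0.1))
  out <- staged_meta(mat, pat, stage2 = s2)
  # two-step: parental meta first, then with stage 2
  for (j in c(1, 7, 19)) {
    par <- ivw_meta(c(mat$log_or[j], pat$log_or[j]),
                    c(mat$se_log_or[j], pat$se_log_or[j]))
    two <- ivw_meta(c(par$log_or, s2$log_or[j]), c(par$se, s2$se_log_or[j]))
    expect_equal(out$log_or_meta[out$snp_id == ids[j]], two$log_or,
                 tolerance = 1e-12)
    expect_equal(out$se_meta[out$snp_id == ids[j]], two$se,
                 tolerance = 1e-12)
  }
})

test_that("allele harmonization flips swapped records and drops mismatches", {
  ref <- cc_table("rs1", 0.2, 0.05, a1 = "A", a2 = "G")
  swapped <- cc_table("rs1", -0.2, 0.05, a1 = "G", a2 = "A")
  out <- harmonize_alleles(swapped, ref)
  expect_equal(out$log_or, 0.2)
  expect_equal(out$a1, "A")
  bad <- cc_table("rs1", 0.2, 0.05, a1 = "C", a2 = "T")
  out2 <- harmonize_alleles(bad, ref)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_unreconcilable"), 1L)
  pal <- cc_table("rs1", 0.1, 0.05, a1 = "A", a2 = "T")
  expect_warning(harmonize_alleles(pal, cc_table("rs1", 0, 1, "A", "T")),
                 "palindromic")
  # staged_meta applies the flip before combining
  m <- staged_meta(ref, swapped)
  expect_equal(m$direction, "++??")
  expect_equal(m$log_or_meta, 0.2, tolerance = 1e-12)
})

test_that("sign concordance: identity, negation, simulated cohorts", {
  tab <- cc_table(paste0("rs", 1:10), rnorm(10), 0.05)
  self <- sign_concordance(tab, tab)
  expect_equal(self$n_concordant, self$n_total)
  flipped <- tab; flipped$log_or <- -flipped$log_or
  none <- sign_concordance(tab, flipped)
  expect_equal(none$n_concordant, 0L)
  expect_error(sign_concordance(tab, cc_table("zz", 1, 1)), "shared")
  # well-powered causal SNPs agree in sign across independent cohorts
  cfg1 <- ideal_config(n_offspring = 15000, n_snps = 30, n_causal = 5,
                       causal_log_or = log(1.4), seed = 201)
  cfg2 <- ideal_config(n_offspring = 15000, n_snps = 30, n_causal = 5,
                       causal_log_or = log(1.4), seed = 202)
  co1 <- simulate_cohort(cfg1)
  co2 <- simulate_trio_genotypes(cfg2)
  co2$truth <- co1$truth  # same causal architecture, independent draw
  co2 <- simulate_parent_disease(co2, "maternal")
  co2 <- simulate_parent_disease(co2, "paternal")
  co2 <- simulate_ages_and_covariates(co2)
  co2 <- apply_reporting_and_exclusions(co2)
  g1 <- transform_table(run_proxy_gwas(co1, "maternal"))
  g2 <- transform_table(run_proxy_gwas(co2, "maternal"))
  causal <- co1$truth$snp_id[co1$truth$causal]
  sc <- sign_concordance(g1, g2, snps = causal)
  expect_equal(sc$n_concordant, sc$n_total)
})
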