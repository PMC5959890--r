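test_that("compute_ld basics: self, duplicate, independence, window", {
  set.seed(2)
  n <- 10000
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 2, 0.4)
  panel <- cbind(a = x, b = x, c = y, d = rep(1, n))
  bp <- c(100L, 200L, 300L, 2e6L)
  expect_warning(ld <- compute_ld(panel, bp), "monomorphic")
  expect_equal(diag(ld$r2)[1:3], c(a = 1, b = 1, c = 1))
  expect_equal(ld$r2["a", "b"], 1, tolerance = 1e-12)
  expect_lt(ld$r2["a", "c"], 0.01)          # independent draws
  expect_equal(ld$r2["a", "d"], 0)          # beyond window -> treated 0
  expect_true(ld$monomorphic["d"])
  expect_true(is.na(ld$r2["c", "d"]) || ld$r2["c", "d"] == 0)
  expect_true(isSymmetric(ld$r2[1:3, 1:3]))
  expect_error(compute_ld(panel[1, , drop = FALSE], bp), "2 individuals")
})

test_that("independent selection matches exhaustive enumeration", {
  # planted 6-SNP instance with LD blocks
  r2 <- matrix(0, 6, 6)
  r2[1, 2] <- 0.9; r2[1, 3] <- 0.7; r2[2, 3] <- 0.65
  r2[4, 5] <- 0.8
  ids <- paste0("s", 1:6)
  ld <- planted_ld(r2, bp = c(1e5, 1.2e5, 1.4e5, 5e6, 5.05e6, 9e6), ids)
  st <- stats_stub(p = c(1e-12, 1e-9, 1e-10, 1e-15, 1e-8, 1e-9),
                   bp = ld$bp, snp_id = ids)
  got <- independent_significant(st, ld)
  sols <- brute_force_select(st, ld$r2, ids, 0.6)
  expect_length(sols, 1L)
  expect_setequal(got$independent, sols[[1]])
  expect_setequal(got$independent, c("s1", "s4", "s6"))
  # non-selected significant SNPs are assigned to a correlated selectee
  expect_equal(unname(got$assignment["s2"]), "s1")
  expect_equal(unname(got$assignment["s5"]), "s4")
  # nothing significant -> empty
  st2 <- st; st2$p <- rep(0.5, 6)
  expect_length(independent_significant(st2, ld)$independent, 0L)
})

test_that("two significant SNPs in strong LD keep only the smaller p", {
  r2 <- matrix(0, 2, 2); r2[1, 2] <- 0.9
  ld <- planted_ld(r2, bp = c(100, 200), c("a", "b"))
  st <- stats_stub(p = c(1e-9, 1e-20), bp = c(100, 200),
                   snp_id = c("a", "b"))
  got <- independent_significant(st, ld)
  expect_equal(got$independent, "b")
})

test_that("lead selection matches exhaustive enumeration on planted blocks", {
  # 3 planted lead blocks among 5 independents (r2 between 0.1 and 0.6)
  r2 <- matrix(0, 5, 5)
  r2[1, 2] <- 0.3; r2[3, 4] <- 0.25; r2[2, 3] <- 0.05; r2[4, 5] <- 0.02
  ids <- paste0("s", 1:5)
  ld <- planted_ld(r2, bp = c(1:5) * 1e5, ids)
  st <- stats_stub(p = c(1e-10, 1e-9, 1e-12, 1e-11, 1e-8),
                   bp = ld$bp, snp_id = ids)
  got <- lead_snps(ids, st, ld, r2_lead = 0.1)
  sols <- brute_force_select(st, ld$r2, ids, 0.1)
  expect_length(sols, 1L)
  expect_setequal(got$leads, sols[[1]])
  # pairwise r2 below the lead threshold
  if (length(got$leads) > 1) {
    rr <- ld$r2[got$leads, got$leads]
    expect_true(all(rr[upper.tri(rr)] < 0.1))
  }
  # a single independent SNP is its own lead
  one <- lead_snps("s1", st, ld)
  expect_equal(one$leads, "s1")
  # two independents at r2 = 0.3 -> one lead
  two <- lead_snps(c("s1", "s2"), st, ld)
  expect_equal(two$leads, "s1")
})

test_that("loci merge leads within 250 kb and collect LD members", {
  # two signals 2 Mb apart; second has a pair of leads 100 kb apart
  ids <- paste0("s", 1:7)
  bp <- c(1.00e6, 1.05e6,                 # locus 1: lead + member
          3.00e6, 3.10e6, 3.05e6,        # locus 2: two leads + member
          3.02e6,                        # locus 2 member (not significant)
          8.00e6)                        # isolated significant SNP
  r2 <- matrix(0, 7, 7)
  r2[1, 2] <- 0.8
  r2[3, 5] <- 0.7; r2[4, 5] <- 0.05; r2[3, 6] <- 0.65; r2[3, 4] <- 0.02
  ld <- planted_ld(r2, bp, ids)
  st <- stats_stub(p = c(1e-12, 1e-9, 1e-14, 1e-10, 1e-9, 0.2, 1e-8),
                   bp = bp, snp_id = ids)
  loci <- clump_loci(st, ld)
  expect_equal(nrow(loci), 3L)
  l2 <- loci[loci$start <= 3.0e6 & loci$end >= 3.0e6, ]
  expect_equal(l2$n_lead, 2L)                     # s3 and s4 merged (100 kb)
  expect_true("s6" %in% l2$member_snps[[1]])      # sub-threshold member
  expect_equal(l2$start, 3.00e6)
  expect_equal(l2$end, 3.10e6)
  iso <- loci[loci$top_lead == "s7", ]
  expect_equal(iso$start, iso$end)                # single-SNP locus
  expect_equal(iso$start, 8.00e6)
  # every significant SNP is a member of exactly one locus
  sig <- st$snp_id[st$p < 5e-8]
  membership <- vapply(sig, function(s)
    sum(vapply(loci$member_snps, function(m) s %in% m, logical(1))),
    numeric(1))
  expect_true(all(membership == 1))
})

test_that("lead merge is transitive across a chain within 250 kb", {
  # three leads: 1-2 and 2-3 within 250 kb, 1-3 beyond -> one locus
  ids <- paste0("s", 1:3)
  bp <- c(1.0e6, 1.2e6, 1.4e6)
  ld <- planted_ld(matrix(0, 3, 3), bp, ids)
  st <- stats_stub(p = c(1e-9, 1e-10, 1e-11), bp = bp, snp_id = ids)
  loci <- clump_loci(st, ld)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_lead, 3L)
  expect_equal(loci$start, 1.0e6)
  expect_equal(loci$end, 1.4e6)
})

test_that("greedy equals brute force on randomized small instances", {
  set.seed(99)
  for (rep in 1:8) {
    k <- sample(4:9, 1)
    ids <- paste0("s", seq_len(k))
    bp <- sort(sample.int(5e6, k))
    r2 <- matrix(0, k, k)
    r2[upper.tri(r2)] <- sample(c(0, 0.05, 0.3, 0.65, 0.9),
                                k * (k - 1) / 2, TRUE)
    ld <- planted_ld(r2, bp, ids)
    st <- stats_stub(p = 10^runif(k, -15, -8), bp = bp, snp_id = ids)
    got <- independent_significant(st, ld)
    sols <- brute_force_select(st, ld$r2, ids, 0.6)
    expect_length(sols, 1L)
    expect_setequal(got$independent, sols[[1]])
    leads <- lead_snps(got$independent, st, ld)
    sols_lead <- brute_force_select(st, ld$r2, got$independent, 0.1)
    expect_setequal(leads$leads, sols_lead[[1]])
  }
})
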