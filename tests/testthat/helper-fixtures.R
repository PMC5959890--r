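# Small-cohort config for fast unit tests
tiny_config <- function(n_offspring = 1000, n_snps = 50, n_causal = 5,
                        causal_log_or = log(1.3), seed = 101, ...) {
  sim_config(n_offspring = n_offspring, n_snps = n_snps,
             n_causal = n_causal, causal_log_or = causal_log_or,
             seed = seed, ...)
}

# Ideal-reporting config: no misclassification, no exclusions
ideal_config <- function(...) {
  args <- utils::modifyList(
    list(report_sensitivity = 1, report_specificity = 1,
         p_dead_before_60 = 0, p_missing_age = 0,
         parent_age_mean = 78, parent_age_sd = 2),
    list(...))
  do.call(tiny_config, args)
}

# Build an ld_matrix object directly from a planted r2 matrix
planted_ld <- function(r2, bp, snp_id = paste0("s", seq_len(nrow(r2)))) {
  diag(r2) <- 1
  r2[lower.tri(r2)] <- t(r2)[lower.tri(r2)]
  dimnames(r2) <- list(snp_id, snp_id)
  structure(list(r2 = r2, r = sqrt(r2), bp = bp, snp_id = snp_id,
                 monomorphic = rep(FALSE, nrow(r2))),
            class = "ld_matrix")
}

# association-stat stub for clumping tests
stats_stub <- function(p, bp, snp_id = paste0("s", seq_along(p)), chr = 1L) {
  data.frame(snp_id = snp_id, chr = chr, bp = bp, p = p,
             stringsAsFactors = FALSE)
}

# Independent enumeration oracle for greedy LD clumping: the selected set
# S is characterized by: s in S  iff  r2(s, s') < thr for every s' in S
# with higher priority (smaller p; ties by bp then id). Enumerate all
# subsets of significant SNPs and return those satisfying the fixed-point
# property (unique).
brute_force_select <- function(stats, r2, snp_ids, thr) {
  ord <- order(stats$p, stats$bp, stats$snp_id)
  ids <- stats$snp_id[ord]
  ids <- ids[ids %in% snp_ids]
  k <- length(ids)
  rr <- r2[ids, ids, drop = FALSE]
  solutions <- list()
  for (mask in 0:(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    ok <- TRUE
    for (i in seq_len(k)) {
      higher <- which(inset[seq_len(i - 1L)])
      belongs <- length(higher) == 0L || all(rr[i, higher] < thr)
      if (belongs != inset[i]) { ok <- FALSE; break }
    }
    if (ok) solutions[[length(solutions) + 1L]] <- ids[inset]
  }
  solutions
}
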