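#' Pairwise LD (r-squared) from a reference dosage panel
#'
#' Squared Pearson correlation of dosage vectors between all SNP pairs
#' within a base-pair window; pairs farther apart than the window are set
#' to 0 (treated as unlinked). Monomorphic SNPs have undefined
#' correlation and are flagged (their rows/columns carry `NA`).
#'
#' @param dosage Reference panel matrix, individuals x SNPs, columns in
#'   position order.
#' @param bp Integer vector of 1-based positions, one per SNP, sorted.
#' @param window_bp Maximum pair distance for which LD is computed
#'   (default 1 Mb).
#' @param snp_id Optional SNP identifiers for dimnames.
#' @return A list of class `"ld_matrix"` with `r2` (symmetric matrix,
#'   unit diagonal), `r` (signed correlations, same support), `bp`,
#'   `snp_id`, `monomorphic` (logical).
#' @export
compute_ld <- function(dosage, bp, window_bp = 1e6, snp_id = colnames(dosage)) {
  if (nrow(dosage) < 2L) stop("reference panel needs >= 2 individuals",
                              call. = FALSE)
  m <- ncol(dosage)
  stopifnot(length(bp) == m)
  if (is.unsorted(bp)) stop("SNPs must be sorted by position", call. = FALSE)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(m))
  mono <- apply(dosage, 2L, stats::var) == 0
  if (any(mono)) warning(sum(mono), " monomorphic SNP(s): r2 undefined")
  r <- suppressWarnings(stats::cor(dosage))
  r[mono, ] <- NA_real_; r[, mono] <- NA_real_
  far <- abs(outer(bp, bp, "-")) > window_bp
  r[far] <- 0
  diag(r) <- ifelse(mono, NA_real_, 1)
  dimnames(r) <- list(snp_id, snp_id)
  out <- list(r2 = r^2, r = r, bp = bp, snp_id = snp_id, monomorphic = mono)
  class(out) <- "ld_matrix"
  out
}

# shared ordering: ascending p, ties by position then id
clump_order <- function(stats) {
  order(stats$p, stats$bp, stats$snp_id)
}

ld_lookup <- function(ld, ids) {
  r2 <- ld$r2[ids, ids, drop = FALSE]
  r2[is.na(r2)] <- 0  # undefined LD treated as independence
  r2
}

#' Independent significant SNPs by greedy LD clumping
#'
#' Selects, among genome-wide significant SNPs, a set that is mutually
#' independent at the given r-squared threshold: candidates are visited
#' in ascending-p order (ties by position, then id) and enter the set iff
#' their LD with every already-selected SNP is below the threshold.
#' Significant SNPs not entering are assigned to the first selected SNP
#' they are correlated with.
#'
#' @param stats Association or meta table with `snp_id`, `bp`, and a
#'   p-value column (`p` or `p_meta`).
#' @param ld An `ld_matrix` from [compute_ld()].
#' @param p_threshold Significance threshold (default 5e-8).
#' @param r2_indep Independence threshold (default 0.6).
#' @return A list with `independent` (snp ids, selection order) and
#'   `assignment` (named character: each significant SNP's independent
#'   SNP).
#' @export
independent_significant <- function(stats, ld, p_threshold = 5e-8,
                                    r2_indep = 0.6) {
  stats <- normalize_pcol(stats)
  sig <- stats[stats$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(independent = character(0),
                assignment = stats::setNames(character(0), character(0))))
  sig <- sig[clump_order(sig), , drop = FALSE]
  r2 <- ld_lookup(ld, sig$snp_id)
  chosen <- integer(0)
  assign_to <- stats::setNames(rep(NA_character_, nrow(sig)), sig$snp_id)
  for (i in seq_len(nrow(sig))) {
    if (length(chosen) == 0L || all(r2[i, chosen] < r2_indep)) {
      chosen <- c(chosen, i)
      assign_to[i] <- sig$snp_id[i]
    } else {
      hit <- chosen[which(r2[i, chosen] >= r2_indep)[1L]]
      assign_to[i] <- sig$snp_id[hit]
    }
  }
  list(independent = sig$snp_id[chosen], assignment = assign_to)
}

#' Lead SNPs within the independent set
#'
#' Greedy selection in ascending-p order among the independent
#' significant SNPs; selected lead SNPs are pairwise below the lead
#' r-squared threshold (default 0.1). Independent SNPs not selected are
#' assigned to their correlated lead.
#'
#' @param independent Character vector of independent significant snp ids.
#' @inheritParams independent_significant
#' @param r2_lead Lead threshold (default 0.1).
#' @return A list with `leads` (snp ids) and `assignment` (named
#'   character: each independent SNP's lead).
#' @export
lead_snps <- function(independent, stats, ld, r2_lead = 0.1) {
  stats <- normalize_pcol(stats)
  sub <- stats[match(independent, stats$snp_id), , drop = FALSE]
  sub <- sub[clump_order(sub), , drop = FALSE]
  r2 <- ld_lookup(ld, sub$snp_id)
  chosen <- integer(0)
  assign_to <- stats::setNames(rep(NA_character_, nrow(sub)), sub$snp_id)
  for (i in seq_len(nrow(sub))) {
    if (length(chosen) == 0L || all(r2[i, chosen] < r2_lead)) {
      chosen <- c(chosen, i)
      assign_to[i] <- sub$snp_id[i]
    } else {
      hit <- chosen[which(r2[i, chosen] >= r2_lead)[1L]]
      assign_to[i] <- sub$snp_id[hit]
    }
  }
  list(leads = sub$snp_id[chosen], assignment = assign_to)
}

#' Define genomic risk loci from leads and independent SNPs
#'
#' Lead SNPs whose positions lie within the merge window (default 250 kb)
#' of each other are merged into one locus, iterated to transitive
#' closure (union-find). Each locus's members are all SNPs in the
#' statistics table — regardless of p-value — whose LD with any of the
#' locus's independent significant SNPs is at least the member threshold
#' (default r2 0.6); a member correlated with independents of several
#' loci goes to the locus of its strongest correlate. Locus boundaries
#' span the member positions; loci left overlapping on the same
#' chromosome after member assignment are merged.
#'
#' @param leads Output of [lead_snps()].
#' @param independents Output of [independent_significant()].
#' @inheritParams independent_significant
#' @param merge_window_bp Lead-merge window in bp (default 250000).
#' @param r2_member Membership LD threshold (default 0.6).
#' @return A data.frame, one row per locus: `locus`, `chr`, `start`,
#'   `end`, `top_lead`, `top_p`, `n_lead`, `n_independent`, `n_member`,
#'   plus list-columns `lead_snps`, `independent_snps`, `member_snps`.
#' @export
define_loci <- function(leads, independents, stats, ld,
                        merge_window_bp = 250000, r2_member = 0.6) {
  stats <- normalize_pcol(stats)
  L <- leads$leads
  if (length(L) == 0L) return(empty_locus_table())
  li <- match(L, stats$snp_id)
  lbp <- stats$bp[li]
  lchr <- if ("chr" %in% names(stats)) stats$chr[li] else rep(1L, length(L))

  # union-find over leads: merge pairs within window on the same chromosome
  parent <- seq_along(L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(L)) for (j in seq_along(L)) {
    if (i < j && lchr[i] == lchr[j] &&
        abs(lbp[i] - lbp[j]) <= merge_window_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_along(L), find, integer(1))

  # map independents to their lead's component
  ind_lead <- leads$assignment[independents$independent]
  ind_comp <- comp[match(ind_lead, L)]

  # members: any SNP with r2 >= threshold to an independent SNP
  r2 <- ld$r2[independents$independent, , drop = FALSE]
  r2[is.na(r2)] <- 0
  loci <- list()
  for (cid in unique(comp)) {
    ind_here <- independents$independent[ind_comp == cid]
    r2_here <- r2[ind_here, , drop = FALSE]
    best <- apply(r2_here, 2L, max)
    # strongest-correlate tie-break across loci
    best_all <- apply(r2, 2L, function(col) {
      w <- which.max(col); ind_comp[w]
    })
    members <- colnames(r2)[best >= r2_member & best_all == cid]
    members <- union(members, ind_here)
    mi <- match(members, stats$snp_id)
    lead_here <- L[comp == cid]
    lp <- stats$p[match(lead_here, stats$snp_id)]
    loci[[length(loci) + 1L]] <- list(
      chr = lchr[match(lead_here[1L], L)],
      start = min(stats$bp[mi]), end = max(stats$bp[mi]),
      lead_snps = lead_here, independent_snps = ind_here,
      member_snps = members[order(stats$bp[mi])],
      top_lead = lead_here[which.min(lp)], top_p = min(lp)
    )
  }
  # merge loci whose spans overlap on the same chromosome
  loci <- merge_overlapping_loci(loci, stats)
  ord <- order(vapply(loci, `[[`, numeric(1), "chr"),
               vapply(loci, `[[`, numeric(1), "start"))
  loci <- loci[ord]
  data.frame(
    locus = seq_along(loci),
    chr = vapply(loci, `[[`, numeric(1), "chr"),
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    top_lead = vapply(loci, `[[`, character(1), "top_lead"),
    top_p = vapply(loci, `[[`, numeric(1), "top_p"),
    n_lead = vapply(loci, function(l) length(l$lead_snps), integer(1)),
    n_independent = vapply(loci, function(l) length(l$independent_snps),
                           integer(1)),
    n_member = vapply(loci, function(l) length(l$member_snps), integer(1)),
    lead_snps = I(lapply(loci, `[[`, "lead_snps")),
    independent_snps = I(lapply(loci, `[[`, "independent_snps")),
    member_snps = I(lapply(loci, `[[`, "member_snps")),
    stringsAsFactors = FALSE
  )
}

merge_overlapping_loci <- function(loci, stats) {
  repeat {
    merged <- FALSE
    for (i in seq_along(loci)) {
      for (j in seq_along(loci)) {
        if (i >= j) next
        a <- loci[[i]]; b <- loci[[j]]
        if (a$chr == b$chr && a$start <= b$end && b$start <= a$end) {
          lead_all <- c(a$lead_snps, b$lead_snps)
          lp <- stats$p[match(lead_all, stats$snp_id)]
          loci[[i]] <- list(
            chr = a$chr,
            start = min(a$start, b$start), end = max(a$end, b$end),
            lead_snps = lead_all,
            independent_snps = union(a$independent_snps, b$independent_snps),
            member_snps = union(a$member_snps, b$member_snps),
            top_lead = lead_all[which.min(lp)], top_p = min(lp)
          )
          loci[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(loci)
  }
}

empty_locus_table <- function() {
  data.frame(locus = integer(0), chr = numeric(0), start = numeric(0),
             end = numeric(0), top_lead = character(0), top_p = numeric(0),
             n_lead = integer(0), n_independent = integer(0),
             n_member = integer(0))
}

normalize_pcol <- function(stats) {
  if (!"p" %in% names(stats)) {
    if ("p_meta" %in% names(stats)) stats$p <- stats$p_meta
    else stop("no p-value column (`p` or `p_meta`)", call. = FALSE)
  }
  if (!"bp" %in% names(stats)) stop("`bp` column required", call. = FALSE)
  stats
}

#' Full clumping pipeline
#'
#' Runs [independent_significant()], [lead_snps()] and [define_loci()]
#' with the standard thresholds (p < 5e-8, independence r2 < 0.6, lead
#' r2 < 0.1, 250 kb merge).
#'
#' @inheritParams define_loci
#' @inheritParams independent_significant
#' @param r2_lead Lead threshold.
#' @return The locus table from [define_loci()], with the independent and
#'   lead sets as attributes.
#' @export
clump_loci <- function(stats, ld, p_threshold = 5e-8, r2_indep = 0.6,
                       r2_lead = 0.1, merge_window_bp = 250000,
                       r2_member = 0.6) {
  ind <- independent_significant(stats, ld, p_threshold, r2_indep)
  if (length(ind$independent) == 0L) return(empty_locus_table())
  ld_leads <- lead_snps(ind$independent, stats, ld, r2_lead)
  out <- define_loci(ld_leads, ind, stats, ld, merge_window_bp, r2_member)
  attr(out, "independent") <- ind
  attr(out, "leads") <- ld_leads
  out
}
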