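#' Map SNPs to genes by position
#'
#' Assigns each variant to every gene whose body (1-based, inclusive),
#' optionally extended by a symmetric window, contains the variant's
#' position.
#'
#' @param variants Data.frame with `snp_id`, `chr`, `bp`.
#' @param genes Data.frame with `chr`, `start`, `end`, `gene`
#'   (see [read_gene_annotation()]).
#' @param window_bp Symmetric extension of the gene body in bp
#'   (default 0).
#' @return Named list, one character vector of snp ids per gene (genes
#'   with no SNPs are dropped).
#' @export
map_snps_to_genes <- function(variants, genes, window_bp = 0) {
  stopifnot(all(c("snp_id", "chr", "bp") %in% names(variants)),
            all(c("chr", "start", "end", "gene") %in% names(genes)))
  if (any(genes$end < genes$start))
    stop("degenerate gene annotation: end < start", call. = FALSE)
  gdt <- data.table::data.table(
    chr = genes$chr,
    start = genes$start - window_bp,
    end = genes$end + window_bp,
    gene = genes$gene
  )
  vdt <- data.table::data.table(
    chr = variants$chr, start = variants$bp, end = variants$bp,
    snp_id = variants$snp_id
  )
  data.table::setkey(gdt, chr, start, end)
  ov <- data.table::foverlaps(vdt, gdt, type = "within", nomatch = NULL)
  split(ov$snp_id, ov$gene)
}

#' SNP-wise mean gene-based test
#'
#' Gene statistic: the mean of the gene's SNP chi-square statistics,
#' `T = mean(z^2)`. Because the SNP z statistics are correlated through
#' LD, the null distribution of `T` is that of a mean of correlated
#' chi-square(1) variables; it is estimated either by Monte Carlo draws
#' from a zero-mean multivariate normal with the reference-panel signed
#' correlation matrix (default), or by a moment-matched scaled
#' chi-square (Satterthwaite) approximation using
#' `E[T] = 1`, `Var[T] = 2 sum(r^2) / m^2`.
#'
#' @param z Numeric vector of SNP z statistics for the gene's SNPs.
#' @param r Signed LD correlation matrix for the same SNPs (repaired by
#'   clipping negative eigenvalues at zero if needed).
#' @param method `"monte_carlo"` or `"satterthwaite"`.
#' @param n_draws Number of Monte Carlo draws (default 1e6).
#' @param seed Optional seed for the Monte Carlo null.
#' @return A one-row data.frame: `n_snps`, `stat`, `p_gene`, `method`.
#' @export
gene_test <- function(z, r = diag(length(z)),
                      method = c("monte_carlo", "satterthwaite"),
                      n_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  m <- length(z)
  if (m == 0L) stop("gene has no SNPs", call. = FALSE)
  r <- as.matrix(r)
  stopifnot(nrow(r) == m, ncol(r) == m)
  stat <- mean(z^2)

  if (method == "satterthwaite") {
    vr <- 2 * sum(r^2) / m^2     # Var of mean of correlated chi-sq(1)
    scale <- vr / 2              # T ~ scale * chisq(df), matched moments
    df <- 2 / vr
    p <- stats::pchisq(stat / scale, df = df, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ev <- eigen(r, symmetric = TRUE)
    vals <- ev$values
    if (min(vals) < -1e-6 * max(abs(vals)))
      stop("correlation matrix is not positive semi-definite beyond repair",
           call. = FALSE)
    vals[vals < 0] <- 0
    A <- ev$vectors %*% diag(sqrt(vals), m)
    # draws in blocks to bound memory at large n_draws
    block <- max(1L, min(n_draws, floor(5e6 / m)))
    exceed <- 0
    done <- 0
    while (done < n_draws) {
      nb <- min(block, n_draws - done)
      Z <- matrix(stats::rnorm(nb * m), m, nb)
      t0 <- colMeans((A %*% Z)^2)
      exceed <- exceed + sum(t0 >= stat)
      done <- done + nb
    }
    p <- (exceed + 1) / (n_draws + 1)
  }
  data.frame(n_snps = m, stat = stat, p_gene = p, method = method,
             stringsAsFactors = FALSE)
}

#' Gene-based analysis over all genes
#'
#' Runs [map_snps_to_genes()] and [gene_test()] per gene on a GWAS or
#' meta-analysis table, using signed LD from the reference panel.
#'
#' @param stats Table with `snp_id`, `chr`, `bp` and a z column (`zstat`
#'   or `z_meta`).
#' @param genes Gene annotation data.frame.
#' @param ld An `ld_matrix` from [compute_ld()].
#' @param window_bp SNP-to-gene assignment window.
#' @inheritParams gene_test
#' @return Data.frame: `gene`, `chr`, `start`, `end`, `n_snps`, `stat`,
#'   `p_gene`, `method`.
#' @export
gene_analysis <- function(stats, genes, ld, window_bp = 0,
                          method = c("monte_carlo", "satterthwaite"),
                          n_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  zcol <- intersect(c("zstat", "z_meta"), names(stats))[1]
  if (is.na(zcol)) stop("no z column (`zstat` or `z_meta`)", call. = FALSE)
  mapping <- map_snps_to_genes(stats, genes, window_bp)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(mapping), function(g) {
    ids <- intersect(mapping[[g]], ld$snp_id)
    ids <- ids[!ld$monomorphic[match(ids, ld$snp_id)]]
    if (length(ids) == 0L) return(NULL)
    z <- stats[[zcol]][match(ids, stats$snp_id)]
    r <- ld$r[ids, ids, drop = FALSE]
    gi <- match(g, genes$gene)
    cbind(data.frame(gene = g, chr = genes$chr[gi], start = genes$start[gi],
                     end = genes$end[gi], stringsAsFactors = FALSE),
          gene_test(z, r, method = method, n_draws = n_draws))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(18251)  # 2.7e-06
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1L) stop("`n_tests` must be at least 1", call. = FALSE)
  alpha / n_tests
}

#' Fisher exact gene-set enrichment
#'
#' For each gene set, compares the number of significant genes in the set
#' with the number expected under independence using the one-sided
#' (enrichment) Fisher exact test on the 2x2 set-by-significance table
#' over the gene universe.
#'
#' @param significant Character vector of significant gene ids.
#' @param sets Named list of character vectors (gene sets); members
#'   outside the universe are ignored.
#' @param universe Character vector of all tested genes.
#' @return Data.frame: `set`, `n_set`, `n_sig_in_set`, `expected`,
#'   `fold`, `p`.
#' @export
fisher_gene_set <- function(significant, sets, universe) {
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  universe <- unique(universe)
  significant <- intersect(significant, universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    a <- length(intersect(s, significant))             # sig in set
    b <- length(s) - a                                 # non-sig in set
    c_ <- length(significant) - a                      # sig outside
    d <- length(universe) - length(s) - c_             # non-sig outside
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                             alternative = "greater")
    expected <- length(s) * length(significant) / length(universe)
    data.frame(set = nm, n_set = length(s), n_sig_in_set = a,
               expected = expected,
               fold = if (expected > 0) a / expected else NA_real_,
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
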