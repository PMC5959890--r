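---
title: "Methods: proxy-phenotype GWAS with a simulated trio cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proxy-phenotype GWAS with a simulated trio cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The proxy-phenotype design

Case ascertainment is the bottleneck of genetic studies of late-onset
diseases such as Alzheimer's dementia: prevalent cases are hard to
recruit and incident cases require decades of follow-up. GWAS-by-proxy
sidesteps this by genotyping healthy offspring and using the
*self-reported disease status of their parents* as the phenotype. Each
offspring shares half of each parent's alleles, so a variant with
per-allele log-odds $\beta$ on parental disease shows up in the
offspring-genotype regression with roughly half that effect. The
pipeline implemented here follows the standard recipe:

1. build maternal and paternal history phenotypes with age-based
   exclusions;
2. regress covariate-residualized status on each SNP dosage (additive
   linear model);
3. convert the linear coefficients to allelic odds ratios from the
   observed prevalence and allele frequency, and double the log-odds to
   put them on the conventional case-control scale;
4. combine cohorts by standard-error-weighted (inverse-variance)
   fixed-effects meta-analysis with a staged design;
5. clump the results into independent significant SNPs, lead SNPs and
   genomic risk loci, and run SNP-wise mean gene-based tests with an
   LD-aware null.

Because the real cohorts behind such analyses are access-restricted,
the package ships a trio simulator that reproduces the statistical
structure the method relies on and retains the generative truth, so
every stage can be validated by parameter recovery rather than by
re-analysis of protected data.

## The simulator

`sim_config()` / `simulate_cohort()` generate, per offspring, a
mother-father-child trio:

* **Genotypes.** Per-SNP minor allele frequencies are drawn uniformly
  from `maf_range` (default 0.05-0.5). Parents are Hardy-Weinberg at
  those frequencies; the child receives one allele drawn uniformly from
  each parent's two. This yields the parent-offspring dosage
  correlation of exactly 1/2 in expectation — the fact that justifies
  the ×2 rescaling below. SNPs are mutually independent (no LD along
  the simulated chromosome); LD enters only through the reference-panel
  machinery of the clumping and gene-based modules.
* **Disease.** Parental disease is logistic in the parent's own
  genotype, $P(D=1\mid g)=\mathrm{logit}^{-1}(\alpha+\sum_j\beta_j
  g_j)$, with `n_causal` SNPs (default 50) of per-allele log-odds
  `causal_log_or` (default 0.18). The intercept $\alpha$ is calibrated
  by bisection so the population-average risk over the simulated
  genotype distribution equals the configured prevalence to within
  1e-6: maternal 0.096 and paternal 0.055 by default, the observed
  sample prevalences of the motivating design (a 1.7-fold maternal
  excess driven by female longevity). A logistic rather than
  liability-threshold model was chosen so the generative truth is
  directly a log-odds, comparable to the recovered odds ratios without
  a scale conversion; the bisection calibration makes the two
  parameterizations agree on what matters (prevalence).
* **Observation.** The offspring's *report* of parental status flips
  the true status with sensitivity 0.85 and specificity 0.99 by default
  — plausible informant-report accuracy; no published estimate pins
  these down, so they are configuration knobs, and the idealized
  recovery experiments set both to 1. Reports are then masked by the
  exclusion rules of the design: parent aged under 60, dead before 60,
  or missing age information. Covariates (assessment centre, batch,
  array, 10 PCs, parental age) are simulated as pure noise by default;
  `covariate_report_effect` can tie reporting probability to the first
  PC to emulate ascertainment artifacts.
* **Determinism.** All randomness flows from `seed`; the seed is stored
  in every cohort and serialized output, and re-running any stage with
  the same inputs is bit-identical.

The default of 10 simulated PCs (the full design used 40) keeps
desk-scale fidelity; the covariate count is immaterial to the method
because the covariates are orthogonal to genotype by construction.

What the simulator does *not* emulate: linkage disequilibrium between
neighbouring simulated SNPs, population structure beyond the PC
covariates, imputation uncertainty, X-chromosome inheritance, sibling
pairs sharing parents, and age-dependent penetrance. Passing tests
therefore demonstrate the *internal* validity of the estimators under
the stated generative model, not robustness to those real-data
complications.

## Association model

The outcome is the residual from a least-squares regression of the
observed status on parental age at death/report, centre, batch, array
and PCs, fitted on that parent's non-missing rows (maternal and
paternal analyses have different analyzed sets, as in the motivating
design; whether residualization used all individuals or the analyzed
subset is not documented there — we use the analyzed subset). Each SNP
is then tested by the simple least-squares slope of the residuals on
dosage; p-values use the normal approximation, indistinguishable from
the t reference at the intended sample sizes and matching the
behaviour of the whole-genome regression tools such summary statistics
come from. SNPs with minor allele frequency ≤ 0.01 are filtered, and an
imputation-quality filter (> 0.3) applies when info scores are
supplied; simulated dosages are exact, so the info filter is inert by
default.

The combined 0/1/2 analysis scores each offspring by the number of
parents *reported* affected, over everyone with at least one parent's
status observed (an excluded parent contributes no case; its missing
age covariate is mean-imputed). Scoring over the union rather than the
intersection of the two parental samples is what makes the combined
GWAS and the maternal+paternal meta-analysis two computations on the
same data: restricted to the intersection, each parental sample loses
~20% of its rows and the per-SNP p-value correlation tops out near
0.83 at desk scale instead of 0.99.

## Odds-ratio conversion and the ×2 rescaling

For a binary trait of prevalence $k$ and effect-allele frequency $p$, a
linear-probability coefficient $\beta$ implies allele-level disease
probabilities $P(D\mid A_1)=k+\beta(1-p)$ and
$P(D\mid A_2)=k-\beta p$, giving the allelic odds ratio

$$\mathrm{OR}=\frac{(k+\beta(1-p))\,(1-k+\beta p)}
                   {(k-\beta p)\,(1-k-\beta(1-p))}.$$

`lmor()` evaluates this and errors, naming the offending factor, when
any implied cell probability is non-positive; `transform_table()`
converts such per-SNP failures into flagged rows instead of aborting a
whole run, and flagged rows are excluded from meta-analysis. Because
the proxy regression sees the parental effect through one meiosis, the
estimated log-odds is about half the parental one; `proxy_scale()`
doubles it (the scaled OR is the square of the unscaled OR). The
standard error is then *derived from the scaled log-odds and the
original p-value*, $\mathrm{SE}=|\log\mathrm{OR}_{\times 2}|/z$ with
$z$ the two-sided normal quantile of $p$ — the unique construction
that leaves the z statistic, and hence the p-value, of the linear test
unchanged. The quantile is evaluated on the log scale so p-values down
to the smallest representable double (e.g. 3.5e-308) do not underflow;
if $p$ is degenerate the linear model's own $z$ is used, which is
identical by construction.

The recovery experiments confirm the scaling empirically: with a true
parental allelic OR of 1.2 and 50,000 trios under perfect reporting,
the unscaled proxy OR converges to $\sqrt{1.2}\approx1.095$ and the
doubled OR to 1.2, with 95% CI coverage near nominal (the acceptance
suite runs 50 replicates of 50,000 trios × 60 SNPs with 6 causal
SNPs). The ground truth in those checks is not `exp(beta)` but the
marginal allelic odds ratio implied by the generative model, computed
by `true_allelic_or()` — by exact enumeration over the causal-genotype
distribution when few causal SNPs exist, by expected-count tabulation
over a large simulated parent population otherwise. Informant-report
misclassification attenuates the estimates; following the motivating
design, the package reports this loss of power (via the recovery
report) but does not correct for it.

## Meta-analysis

`ivw_meta()` is effect-based inverse-variance weighting — METAL's
standard-error scheme, matching the "SE-weighted" description — not
sample-size-weighted z combination. `staged_meta()` implements the
staged design: maternal and paternal proxy cohorts are combined first;
the result is combined with the external study's stage 2 statistics
where a SNP has them, and with stage 1 only otherwise (the quoted
staging; stage-1 effects of stage-2 SNPs are never double-counted).
Fixed-effects IVW is associative, so the staging is a bookkeeping
convention, not a statistical choice — the test suite checks staged
and one-step pooling agree to 1e-12. The 4-character direction string
records each cohort's effect sign in the order (maternal, paternal,
stage 1, stage 2), with `?` for a cohort that did not contribute at
that SNP — so a SNP combined with stage 2 shows `?` in the stage-1
slot. Alleles are harmonized by exact match or swap-with-sign-flip;
palindromic (A/T, C/G) records pass through with a warning since all
in-scope data are self-generated and strand-unambiguous, and
unreconcilable records are dropped with a count. No heterogeneity
statistic is computed (fixed-effects only, as in the source design).

## Locus definition

`compute_ld()` builds r² (and signed r) from a reference dosage panel
within a 1 Mb window (pairs beyond the window are treated as unlinked);
monomorphic SNPs are flagged and treated as uncorrelated. Clumping
follows the FUMA defaults: independent significant SNPs are chosen
greedily in ascending-p order (ties broken by position then identifier
— the published description leaves tie-breaking open) among SNPs with
p < 5e-8, admitting a SNP iff its r² with every already-admitted SNP
is below 0.6; lead SNPs repeat the greedy pass within the independent
set at r² < 0.1; loci merge lead SNPs whose *positions* lie within
250 kb (iterated to transitive closure) and collect as members all
SNPs — no p-value requirement, since the quoted rule imposes none;
`r2_member` is the knob if one is wanted — with r² ≥ 0.6 to any of the
locus's independent SNPs, assigning a member correlated with several
loci to its strongest correlate. Locus boundaries span the members;
loci left overlapping after member assignment are merged so loci on a
chromosome are disjoint. On instances of ≤ 10 significant SNPs the
greedy output is verified against exhaustive enumeration of the
selection fixed-point, which is unique.

## Gene-based testing and enrichment

The gene statistic is the SNP-wise mean chi-square,
$T=\frac1m\sum_j z_j^2$, over the SNPs mapped to the gene body
(window 0 by default; the SNP-to-gene window of the original analysis
is unstated, so it is a configuration knob). The null distribution of
$T$ under LD is taken from the multivariate normal with the
reference-panel signed correlation matrix: by Monte Carlo
(10^6 draws by default, seeded, with eigenvalue clipping at zero to
repair near-PSD matrices) or by a moment-matched scaled chi-square
(Satterthwaite) fast path using $E[T]=1$,
$\mathrm{Var}[T]=2\sum_{ij}r_{ij}^2/m^2$. This is a documented
stand-in for MAGMA's exact machinery, with the same "constant sample
size for all genes" simplification (no per-SNP N weighting); the two
paths agree within Monte Carlo error for the gene sizes tested, and
both are exact for a single SNP and for independent SNPs. Significance
uses Bonferroni only (0.05 divided by the number of genes), and
gene-set enrichment is the one-sided Fisher exact test of significant
genes in the set against the expected count — enrichment, not
two-sided, matching the "compared with the expected number" design.

## Diagnostics

* `overlap_sensitivity()` compares the combined 0/1/2 GWAS with the
  maternal+paternal meta-analysis: Pearson correlation of per-SNP
  p-values (raw, as the headline number is phrased, and on −log10,
  which the companion regression uses — the phrasing is ambiguous, so
  both are reported) plus the −log10 regression intercept and slope.
  On the standard simulated cohort (20,000 offspring, 2,000 SNPs, 50
  causal) the suite requires raw-p correlation ≥ 0.98, −log10
  correlation ≥ 0.99, intercept within 0.05 of 0 and slope within 0.05
  of 1.
* `genomic_inflation()` is the median association chi-square over
  `qchisq(0.5, 1)` = 0.4549364 (the exact null median; the constant is
  computed, not hard-coded). Under the global null the suite requires
  λ = 1.00 ± 0.02 on 10^5 null statistics; under the default polygenic
  simulation λ exceeds 1, as expected when true signal is present.
* `effect_concordance()` and `sign_concordance()` quantify agreement
  of log-odds between analyses (e.g. maternal vs paternal) on a SNP
  list after harmonization.
* `recovery_report()` tabulates estimated vs true log-odds at causal
  SNPs with CI coverage, aggregate bias and RMSE, and the ratio of
  unscaled to true log-odds (≈ 0.5, the empirical footing of the ×2
  factor).

## Numerical and design notes

* Problem sizes in the test suite were chosen to make each stochastic
  assertion a ≥ 3-sigma check at desk scale: the null-calibration run
  pools 10^5 independent null statistics for λ and type-I error; the
  recovery experiment uses 50 replicates × 6 causal SNPs at 50,000
  trios; the overlap analysis uses the full 20,000 × 2,000 standard
  cohort.
* All coordinates are 1-based inclusive; A1 is always the effect
  allele; alleles are upper-cased on read. Summary statistics are
  tab-delimited with one header line and round-trip losslessly
  (doubles written at 17 significant digits).
* Degenerate inputs are first-class: monomorphic SNPs are flagged and
  dropped from association and LD (not silently zeroed), all-missing
  statuses warn, constant combined phenotypes error, rank-deficient
  covariate matrices error naming the collinear columns, and per-SNP
  conversion failures are flagged rows rather than fatal.
* Every pipeline stage is a pure function of (inputs, config, seed);
  the CLI logs seed and row counts to standard error.

## Limitations

The simulator's independence of SNPs means locus definition and
gene-based tests are exercised against *planted* or *panel-estimated*
LD rather than realistic recombination structure. The logistic disease
model ignores age-dependent incidence, so the age exclusions act as
missingness, not as informative censoring. Misclassification is
independent of covariates unless explicitly configured. External
(case-control) summary statistics are consumed as given: no
genomic-control correction, LD-score decomposition or heritability
estimation is in scope.
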