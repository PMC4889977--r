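---
title: "Models and methods: sex, the X chromosome, and regulatory variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sex, the X chromosome, and regulatory variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sexqtl` implements a connected set of analyses for asking how sex and the X
chromosome shape the regulatory genome in an expression cohort: do genes
differ between the sexes in expression mean and *variance*; where are
cis-eQTLs and how does the X differ from the autosomes; which regulatory
effects depend on sex (genotype-by-sex interactions, sex-interacting
allele-specific expression); is chromatin accessibility sex-specific and
does it line up with sex-specific expression; and do trait-associated
variants carry cumulatively sex-biased regulatory effects. Every stage can
be exercised on a bundled synthetic cohort with known ground truth, so the
whole pipeline is testable without access to any controlled data.

This vignette is the package's own account of the models, the choices that
were genuinely open, and the numerical details that matter.

## Conventions and X-chromosome dosage

Sex is coded 0 = male, 1 = female everywhere, so positive sex or
interaction coefficients mean "larger in females". Males are hemizygous on
chrX; a male genotype has no heterozygous state. Two codings of the male X
dosage are supported:

* `full_dosage` (default): a male alternate allele is coded 2, so one male
  allele carries the same regression dosage as a female homozygote. This
  matches the dosage-compensation view (one active X per cell in both
  sexes) and is the common practice in X-aware association tools.
* `haploid`: male dosages in {0, 1}.

Both are exposed because association studies have used both; the choice
rescales the male genotype variance (4f(1-f) versus f(1-f)) and therefore
matters for any cross-sex comparison of effect sizes or variance explained.
Allele frequencies on chrX always count one allele per male and two per
female (`sex_aware_maf()`), regardless of the regression coding.

Heterozygous male chrX calls are impossible under hemizygosity; `read_vcf()`
sets them to missing and counts them. Coordinates are 1-based for VCF and
annotation, 0-based half-open for BED peaks. Missing genotypes are dropped
pairwise (complete cases) in every regression.

## Differential variance between the sexes

Expression variance can differ between the sexes even when means do not —
for instance when a regulatory variant is exposed differently by
hemizygosity. Three testing strategies are provided (`test_dv()`), on
residual-scale expression with the sexes matched in number
(`match_subsample()`, seeded, all of the minority sex plus an equal-size
draw of the majority):

* **A** — an F-test of variance equality for every gene.
* **B** — a Shapiro-Wilk normality gate (level `alpha_normality = 0.05`) on
  the pooled within-sex-centered values; genes passing take the F branch,
  genes failing take the Brown-Forsythe branch (one-way ANOVA on absolute
  deviations from the group medians, which is robust to non-normality).
  The gate can instead be applied per sex (`gate_scope = "per_sex"`); the
  pooled default uses all samples and so has the more stable gate.
* **C** — sex is regressed out first and the gate-and-test applied to the
  regression residuals, so that genuine variance differences are separated
  from variance differences induced by a mean (differential-expression)
  difference.

One design point deserves emphasis. A rank-based variant of strategy C —
mapping each gene's values onto normal scores `qnorm((rank - 0.5)/n)`
before the regression — is a common normalization, and
`test_dv(..., qn = "gene")` provides it. But the transform hands both sex
groups a without-replacement partition of one fixed set of scores: the
pooled variance is pinned, the two group variances become strongly
negatively coupled, and the parametric F reference collapses toward 1. The
result is a severely conservative test (the test suite checks that its
size stays below nominal). It is therefore *not* the default;
`qn = "none"` tests the residual-scale values, which under normal errors
makes the F branch exactly calibrated, with the Brown-Forsythe branch
covering heavy-tailed genes. A per-sample normalization margin was also
examined and rejected: it is anticonservative whenever mean shifts differ
across genes, because gene-specific shifts warp each sample's monotone rank
map.

X-versus-autosome contrasts of any per-gene indicator use a one-sided
Fisher's exact test (`xa_proportion_test()`), and the overlap between
variance hits and mean hits is checked with a 2x2 chi-squared test
(`dv_de_overlap_test()`) — no continuity correction, for uniform behaviour
across table shapes.

## cis-eQTL and genotype-by-sex interaction mapping

For gene expression y, genotype g and sex s, the additive model is

    y = mu + b1 g + b2 s + e,        e ~ N(0, sigma^2)

and the interaction model adds `b3 (g x s)`; the interaction p-value is the
Wald t-test of `b3`. Variants are cis to a gene when they fall within 1 Mb
upstream of the genomic TSS through 1 Mb downstream of the genomic TES
(`cis_pairs()`, boundary-inclusive). Fits are ordinary least squares with
classical standard errors, matching the linear-regression framework that
large eQTL scans use. The additive scan runs jointly or within one sex
(dropping the sex column); the interaction scan requires MAF >= 0.05
*within each sex separately* and drops variants whose `{1, g, s}` column
set has numerical rank < 3 (singular values below `1e-8` times the largest
— the rank rule needs an explicit tolerance to be reproducible).

Multiple testing is hierarchical (`gene_level_fdr()`): Bonferroni over the
number of variants actually fitted for the gene, keep the best association
(ties broken lexicographically on variant id so reruns are byte-identical),
then Benjamini-Hochberg across genes' best associations. Only fitted tests
count toward the per-gene Bonferroni; variants excluded by the MAF or rank
filters were never tested and inflating the correction with them would be
arbitrary.

Comparative statistics: discovery-rate depletion on X versus autosomes per
FDR threshold (chi-squared, Bonferroni over the threshold grid), effect-size
magnitude comparisons by two-sided Wilcoxon with optional quantile binning
on a per-gene score (e.g. a selective-constraint measure supplied by the
user), and tail enrichment of interaction p-values via a one-sided Wilcoxon
on the top-K -log10 p from each chromosome class (`qq_enrichment()`).

## Per-sex cis heritability (PVE)

The proportion of expression variance explained by common cis variants is
estimated per gene and per sex stratum from the single-component model
`y = g + e`, `g ~ N(0, sg2 K)`, with K the cis GRM `Z Z'/m` built from
column-standardized dosages (population 1/n denominator, so trace(K) = n
exactly). REML is profiled down to a one-dimensional likelihood in
h2 = sg2/(sg2+se2) via the eigendecomposition of K, maximized on [0, 1]
with explicit boundary checks; a Haseman-Elston regression (cross-products
on GRM entries, clipped to [0, 1]) is available as the moment alternative.
The sexes are compared on equal sample sizes (the female stratum is a
seeded subsample matched to the male count) with a Wilcoxon rank-sum across
genes and the fold of mean PVE.

Under `full_dosage` coding with a shared allelic effect, the male genetic
variance at an X variant is twice the female one (4f(1-f) versus 2f(1-f)),
so male PVE should exceed female PVE on X-linked genes — a directional
prediction of hemizygosity that the validation suite checks on synthetic
truth (`x_biology_run("pve")`).

## Sex-interacting allele-specific expression

Within an individual heterozygous for a regulatory variant, the two
haplotypes are exposed to different regulatory alleles, so allelic read
counts at transcribed heterozygous sites measure the regulatory effect
within the individual. Counts are aggregated per gene x individual
(`aggregate_sites()`, default minimum 10 reads). With h in {-1, 0, +1} the
phased dosage contrast (sign = which haplotype carries the alternate
regulatory allele) and s the sex, the model is a binomial GLMM:

    alt_i ~ Binomial(n_i, logistic(alpha + gamma h_i + delta h_i s_i + u_i)),
    u_i ~ N(0, tau^2)

The random intercept absorbs individual-level allelic-ratio shifts
(reference/mapping bias, cis background). `delta` is the sex-interaction
parameter; its test is a likelihood-ratio test against chi-square(1). The
marginal likelihood integrates u_i by adaptive Gauss-Hermite quadrature:
the integrand is re-centered per individual at its mode (Newton steps on
the conditional posterior) and scaled by its curvature, with 9 nodes by
default — on test fixtures the log-likelihood moves by < 1e-4 between 9
and 15 nodes. With `tau_fixed = 0` the model reduces exactly to logistic
regression (used as a unit-test oracle against `glm`), and estimates agree
with `lme4::glmer(nAGQ = 9)` to ~1e-3 on fixtures. An optional
beta-binomial conditional likelihood (`family = "betabinomial"`) adds an
overdispersion parameter for loci with extra-binomial allelic noise.
Non-convergence after restarts yields a flagged NA fit, never a silent
estimate.

A limitation worth knowing: with one aggregated observation per individual,
tau is weakly identified, and when the truth has tau > 0 the delta LRT is
mildly anticonservative at realistic depths (the statistic itself matches
the reference mixed-model implementation on fixtures, so this is a
property of the design, not the optimizer). Calibration checks therefore
use the tau = 0 null, where the test is accurate; p-values from deeply
overdispersed loci should be read with this in mind, or the beta-binomial
family used.

## Sex-specific chromatin accessibility

Peak counts are normalized by median-of-ratios size factors (exp of the
median log-ratio to the per-peak geometric-mean reference; peaks with
zeros are excluded from the reference, and a library-size fallback with a
warning covers matrices with no all-positive peak). Dispersion is estimated
per peak by method-of-moments on normalized counts — df-weighted pooled
within-group variance v, sampling part z = m * mean(1/sf), alpha =
max(0, (v - z)/m^2) — and then shared across peaks through a mean-dispersion
trend `a0/m + a1` fitted by regression. The trend value is the default
per-peak dispersion (`sharing = "trend"`); `"max"` (the larger of raw and
trend, more conservative) and `"raw"` are available. With small group
sizes the raw per-peak estimate is noisy in both directions; the trend is
what keeps the test's size close to nominal in the calibration suite.

The two-group test is the conditional negative-binomial exact test: given
the peak's total count, the group sums are modeled as independent NB
variables with moments implied by the common rate, the size factors and the
dispersion, and the p-value sums the probabilities of all splits of the
total no more likely than the observed one. The computation is done
entirely in log space with a log-sum-exp reduction; a brute-force
enumeration oracle checks it exactly (to 1e-12) for all totals up to 60.
Sex-specific peaks default to FDR 10%; the threshold is exposed
(`fdr` argument) since reasonable analyses have used both 5% and 10%.

Integration with expression: peaks are linked to genes through a 40-kb
strand-oriented upstream window (minus-strand genes look at higher
coordinates; a genomic-orientation flag exists because the convention is
not universal). Enrichment of gene flags (sex-specific expression,
interaction eQTL) among genes with a linked sex-specific peak is tested by
Fisher's exact test per threshold, and direction concordance — whether the
peak-open sex opposes the expression-up sex — by a one-sided exact binomial
on the discordance count. "Top" X peaks for the X-inactivation-escape
enrichment are ranked by nominal p with |log2 fold| as tie-break, taking
the floored top decile.

## Sex-biased regulatory effects at trait loci

For each trait, catalog variants are LD-pruned greedily (sort by GWAS p,
keep a variant iff r^2 < 0.5 with everything already kept; deterministic id
tie-break; missing r^2 treated as independent with a warning). Each kept
variant must be a cis-eQTL at nominal p < 1e-3 in the joint analysis; among
its cis genes the one with the best joint p is scored (an all-genes mode
would score each, but one gene per variant keeps the per-trait counts
interpretable). The absolute additive effect is then re-estimated in the
male stratum and a seeded female subsample of equal size (274/274 in the
emulated design), and the variant is classified female-biased iff
|beta_f| >= 1.2 |beta_m|, male-biased under the mirror rule — the boundary
counts as biased, since the rule is "1.2-fold greater or more" — and
unclassified otherwise. Traits with at least 20 classified variants get a
two-sided exact binomial test of female-biased among biased variants
against 0.5, Bonferroni-corrected across tested traits. The binomial n
counts only the biased variants (the question is whether one sex dominates
*among* sex-biased effects); unclassified variants dilute neither side.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` mirrors the emulated study design: 648 females and 274
males by default; Hardy-Weinberg genotypes with allele frequencies uniform
on [0.05, 0.5]; X genotypes with male hemizygosity under the chosen coding;
expression built generatively from the same linear model the mapper fits
(effect mixtures for b1/b2/b3 with configurable proportions and SDs;
per-gene sex-specific residual SDs for differential-variance genes;
X-inactivation-escape genes receive a female mean increase in both
expression and their upstream peak); allelic counts from the ASE GLMM
itself (Poisson total depth plus a floor of one read); NB peak counts with
per-sample library factors and sex-specific log-fold shifts; and a GWAS
catalog whose trait variants tag simulated eQTLs, with copy-with-mutation
LD proxies at controlled r^2 for the pruning step. Cis windows of distinct
genes are laid out disjointly, which makes per-gene truths unambiguous.

Deliberately absent: realistic haplotype/LD structure beyond the explicit
proxies, population stratification, cell-type composition (the dominant
confounder in whole blood), hidden technical factors, read-level
reference bias in ASE, and GC effects in ATAC counts. Passing tests on
this cohort therefore demonstrate statistical correctness of the machinery
— calibration, recovery, directional X biology — not robustness to the
biological confounding that real cohorts carry; the covariate-corrected
residual inputs are assumed to have dealt with that upstream.

Effect-size distributions are config choices, not estimates from any real
cohort: defaults (30% of genes with |b1| ~ N(0, 0.3), 20% with sex effects,
10% with interactions, residual SD 1) give the mapper realistic mixed
power at n = 922, which is what a validation cohort needs.

## Validation suite and problem sizes

The package validates itself at these scales (chosen to give tight Monte
Carlo bands while staying desk-scale): exact-test oracle equivalence over
*all* 2x2 tables with total <= 40 and all NB splits with total <= 60;
OLS against closed-form normal equations to 1e-10; type-I error of the
interaction test, DV strategy C, the NB peak test and the ASE LRT on 2000
null units each at cohort-realistic sizes (648/274 samples; 10 + 10 ATAC
samples; 30 heterozygous individuals per sex), required to sit within two
binomial standard errors of 0.05; recovery of b3 = 0.3 (500 replicates,
n = 922, |bias| < 0.02), h2 = 0.3 (200 replicates, n = 500, within 0.05)
and delta = 0.8 (200 replicates, within 0.15); directional X biology over
seeded cohorts (male > female PVE; X eQTL depletion; X interaction
enrichment — each in >= 90% of seeds); realized gene-level FDR <= 0.05
plus two standard errors with 10% true genes over 50 replicates; the
female-biased trait flagged at Bonferroni 0.05 in >= 90% of seeds with
null traits at <= 5%; and byte-identical `run_all()` output trees for a
fixed seed. `scripts/acceptance.R` recomputes the headline numbers from
scratch.

## Known limitations

* The ASE LRT's mild anticonservatism under estimated tau > 0 (above).
* PVE uses a single cis variance component; trans effects and
  multi-component partitions are out of scope, and REML point estimates at
  desk-scale n are noisy for individual genes — the package compares
  distributions across genes, not single-gene values.
* The NB test conditions on totals with moment-matched NB margins; with
  very few samples and extreme size-factor spread the moment matching is
  approximate (the calibration suite covers the realistic regime).
* `run_all()` orchestrates the synthetic cohort end to end; real-data use
  is through the stage functions with user-supplied files. Hidden-factor
  correction is limited to `residualize_expression()` — regression on a
  supplied covariate matrix and/or the leading expression principal
  components (a PCA stand-in for latent-factor methods); full
  latent-factor estimation is out of scope.
* Classical OLS standard errors are the default throughout the mapping
  stage, matching the standard eQTL framework; HC0 sandwich errors are
  available behind the `robust` flag of `fit_additive()` /
  `fit_interaction()` for heteroskedastic residuals.
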