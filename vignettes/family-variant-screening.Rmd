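---
title: "Screening extended pedigrees for trait-associated genes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening extended pedigrees for trait-associated genes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pedscreen` compares eight strategies for flagging candidate genes from
rare and common variants in a handful of extended pedigrees, against a
known causal-gene set. Because the family mini-exome data this design
emulates is access-restricted, the package ships its own generator: a
simulated study with a stated pedigree structure, variant spectrum,
phenotype model and ground truth, so that every downstream claim —
detection, calibration, sensitivity/specificity — is checkable.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open.

## The polygenic variance-components model

All heritability-based approaches rest on the linear mixed model

$$ y = X\beta + g + e, \qquad
   g \sim N(0, \sigma^2_a\, 2\Phi), \quad e \sim N(0, \sigma^2_e I), $$

where $\Phi$ is the pedigree kinship matrix computed by the exact
recursion (founders unrelated, $\phi_{ii} = \tfrac12(1+\phi_{fm})$,
$\phi_{ij} = \tfrac12(\phi_{fj}+\phi_{mj})$), and narrow-sense
heritability is $h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)$ after the fixed
covariates in $X$. `fit_polygenic()` maximizes the REML likelihood by a
Brent search over $h^2 \in [0, 1)$ with the total variance profiled out
analytically; a one-off eigendecomposition of $2\Phi$ rotates the data so
each profile evaluation costs $O(np^2)$. Boundary optima ($\hat h^2 = 0$)
are compared explicitly against the interior candidate, and the standard
error of $\hat h^2$ comes from the numerically observed information of the
profile likelihood (reported `NA` at the boundary, where the information
matrix is degenerate).

Two deliberate modeling choices follow the study being reproduced rather
than best current practice:

* **Binary affection is analyzed as a 0/1 quantitative trait** on the
  observed scale — no liability transformation. The source analysis did
  exactly this (and flagged its software's limitation with binary
  traits); fidelity was preferred over embellishment. Consequences show
  up in calibration: Gaussian likelihood-ratio tests on a 0/1 outcome
  with strongly skewed covariates (rare-allele burdens) are mildly
  conservative in finite samples (measured null rates ~0.04 at nominal
  0.05), which the acceptance tests' tolerance bands acknowledge.
* **Fixed-effect tests use ML, not REML.** REML likelihoods are not
  comparable across fixed-effect designs, so `covariate_test()` refits
  both models by ML for the LRT and reports a Wald p-value alongside;
  heritability bookkeeping (`h2_with`, `h2_without`) uses REML.

The heritability LRT against $\sigma^2_a = 0$ uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, giving $p = 0.5$ at a zero
statistic. At the emulated scale (~700 individuals in 8 pedigrees) the
measured type-I error at 1,000 null replicates is about 0.034 — the
mixture is known to be slightly conservative at finite family counts.

## The eight detection approaches

For a binary affection status with base covariates Age and Q4 (the pair
that maximized trait heritability in the emulated study):

* **A** — per-gene sum of rare minor alleles (synonymous and
  nonsynonymous) as a covariate in the polygenic model.
* **B** — 0/1 indicator of carrying at least one *rare nonsynonymous*
  allele in the gene.
* **C** — sum of minor alleles over the gene's *common* variants.
* **D** — every variant tested family-by-family as a covariate in that
  family's own polygenic model; a variant is selected when it is
  significant *and* lowers the family's $\hat h^2$; a gene is detected
  when any of its variants is selected in any family.
* **E/G** — per-variant linear association on the common (E) or rare (G)
  panel, with the genotype decomposed into a between-family expected
  value $b$ (mean of available parental genotypes; sibship mean when
  parents are untyped; own genotype for isolated founders) and a
  within-family deviation $w = g - b$. The primary p-value tests $b$ and
  $w$ jointly (2 df); the within-only p-value is reported alongside.
* **F/H** — the same $[b, w]$ pair tested jointly inside the polygenic
  model (variance-components association), with pedigree $2\Phi$
  standing in for the gene-specific IBD matrices of the original runs,
  which are not recoverable without the restricted files.

Detection everywhere is $p < 0.05$ with **no multiple-testing
correction** — the comparison's point is the raw behavior of each
strategy, and the source analysis explicitly declined correction.

Approach D's published selection rule ("reducing trait heritability in at
least one family") would by itself select roughly half of all null
variants, since $\hat h^2$ falls or rises by chance almost symmetrically
when a random covariate is added. The implemented rule conjoins the
heritability reduction with covariate significance; this keeps D's
characteristic profile — far more detections than A–C, high sensitivity,
poor positive predictive value — while remaining a defensible test. This
is an interpretation, and it is flagged as such.

Two calibration facts about E and G deserve emphasis. Their *total*
(2 df) association test is anticonservative whenever the trait has
polygenic family correlation, because the between-family component $b$ is
confounded with relatedness — measured null rates around 0.07–0.08 at
nominal 0.05 on polygenic null studies. Their *within* p-value is immune
to this by construction and measures at ~0.05. The acceptance suite
therefore calibrates E and G on the within test; the total test's
inflation is the textbook motivation for the variance-component and
within-family designs, not a defect of the implementation. Relatedly, the
exact-invariance form of that immunity is algebraic only when the
confounding acts through the span of $(1, b)$; an arbitrary per-family
trait shift is neutralized in expectation, which the stratification
simulation verifies operationally.

## Gene-based p-value combination

`gene_based_p()` combines a gene's per-variant p-values into one gene
p-value in the VEGAS style: the observed statistic is
$T = \sum_j F^{-1}_{\chi^2_1}(1-p_j)$, and its null distribution is
simulated by drawing $z \sim N(0, \Sigma)$ with $\Sigma$ the marker
correlation matrix and accumulating $\sum_j z_j^2$. The gene p-value is
$(1 + \#\{T_{sim} \ge T\})/(n_{sims}+1)$, never exactly zero. The
original tool looked $\Sigma$ up from reference-panel LD; here $\Sigma$
is an explicit argument (database retrieval is out of scope), defaulting
in `gene_scores()` to the sample genotype correlation of the gene's
markers. Matrices indefinite beyond $-10^{-6}$ are an error; smaller
negative eigenvalues are clipped to zero (with a warning beyond numerical
noise at $-10^{-12}$). With $k=1$ the statistic reduces to the marker
p-value; with independent markers to the $\chi^2_k$ survival function;
with a perfectly correlated block to the single-marker case — the three
limits the acceptance suite checks at $10^5$ draws.

## Pathway enrichment and evaluation

`enrich_pathways()` performs one-sided hypergeometric over-representation
per pathway, with the universe restricted to genes annotated in at least
one pathway — in the emulated study only about a third of genes had any
annotation, and enrichment within coverage is the only defensible
reading. Tail sums are accumulated in log space. No multiplicity
correction, matching the source.

`confusion()` evaluates a detected-gene set against the causal set over
the whole gene universe (untestable NCV genes count as non-detected —
required to reconcile the published specificity denominators), with
undefined rates reported `NA` rather than 0. `format_rate()` truncates
(not rounds) at three decimals because the published table evidently did:
$1/15 = 0.0666\ldots$ prints as 0.066 and $1/19 = 0.0526\ldots$ as 0.052
only under truncation. Recomputing every published metric cell from the
printed counts reproduces the sensitivity/PPV/NPV columns; four
specificity cells and one PPV cell (approach D: $9/767 = 0.011$ printed
as 0.001) do not follow from the printed counts under any rounding rule
and are treated as errata of the source table, not as targets.

## The synthetic study: what it emulates, what it does not

`sim_config()` defaults state the emulated world: 8 multi-generation
pedigrees re-drawn until each holds 60–120 members (totalling ~697),
3,204 genes with 2–13 variants each (~24,500 variants), 74% of variants
rare (population MAF < 0.01), 70% nonsynonymous, 15 causal genes, 30%
affection prevalence.

* **Pedigrees** grow from one founder couple; each mating draws 3–6
  children and non-terminal children marry in a founder spouse with
  probability 0.75. These three numbers were chosen once to center
  family size near 87 (697/8) and are configurable.
* **Genotypes** come from independent-per-variant founder draws
  (Bernoulli at the population MAF) followed by Mendelian gene-dropping,
  so Mendelian consistency holds by construction and there is no linkage
  disequilibrium — none of the eight approaches uses LD, and the
  gene-based combiner takes $\Sigma$ explicitly. Rare population MAFs
  are drawn Uniform(0.0005, 0.0099), common Uniform(0.01, 0.5). The
  variant table records the population MAF (`maf`, the analogue of a
  supplied annotation file, and the basis of rare/common classification)
  and the realized sample MAF (`maf_sample`). Classification must use
  the population MAF: in a desk-scale sample the realized-MAF rare class
  is structurally near-empty, because any transmitted founder allele is
  amplified by descent past 1% of a small sample. Variants monomorphic
  in the realized sample remain in the table and surface downstream as
  NCV statuses, mirroring the published table's untestable entries.
* **Phenotypes** follow a liability-threshold model. Q1 and Q2 receive
  additive effects from the nonsynonymous variants of their assigned
  causal genes (genes alternate between the two traits), a polygenic
  component with covariance $h^2_{poly}\, 2\Phi$ ($h^2_{poly} = 0.6$ by
  default, matching the emulated study's covariate-adjusted estimate)
  and Gaussian noise; Q4 is polygenic plus noise only, independent of
  causal genes — which also makes Q4 the trait whose true $h^2$ equals
  the configured value exactly, and therefore the parameter-recovery
  target. Liability is
  $0.3\,\mathrm{Age}_{std} + 0.4\,\mathrm{Smoking} + 1.0\,Q1 + 0.5\,Q2
  - 0.8\,Q4 + \varepsilon$; the signs reproduce the published
  odds-ratio directions (Q4 protective; Age, Smoking, Q1, Q2 risk) and
  the magnitudes are otherwise unconstrained choices. Affection is
  liability above its empirical $(1-\text{prevalence})$ quantile, so the
  realized prevalence is within $1/n$ of the target by construction.
  Age ~ Uniform(20, 80), Smoking ~ Bernoulli(0.2), Sex from the
  pedigree; none is stated by the source, all are configurable.
* **Per-variant causal effects** scale as
  $\beta_v = \beta_0 \log_{10}(f_v)/\log_{10}(0.005)$, so `effect_size`
  ($\beta_0$, default 0.5 SD) is the per-allele shift of a MAF = 0.005
  variant, ultra-rare variants get proportionally larger effects and
  common ones attenuated. A constant $\beta$ across all causal
  nonsynonymous variants would let the causal genes' common variants
  add ~0.6 SD² of additive variance and push Q1's true heritability far
  above the configured polygenic value; the frequency-dependent form
  keeps recovery meaningful and matches the rarer-is-larger architecture
  of the emulated simulation.

What a green test on this generator does **not** establish: behavior
under LD (none is simulated), genotyping error or missingness mechanisms
(missingness is uniform at a configurable rate, 0 by default), the exact
undisclosed phenotype model of the original workshop data, or
liability-scale heritability of the binary trait.

## Numerical choices and degenerate inputs

* Brent tolerance $10^{-8}$ on $h^2$; the optimizer's answer is compared
  against both boundaries before accepting.
* $K \propto I$ raises a non-identifiability error; rank-deficient
  designs name the collinear columns; trait permutation or translation
  by design columns are covered by invariance tests.
* Kinship ties and cycles: half-founders are rejected (add a dummy
  founder), ancestry cycles are reported with the individuals involved.
* Minor-allele recoding in `read_ped()` uses the realized frequency over
  all genotyped individuals; a 0.5/0.5 tie keeps the lexicographically
  smaller allele label as the reference, making recoding deterministic.
* Burdens treat missing genotypes as 0 and flag genes where >20% of
  individuals have missing calls; monomorphic-in-sample covariates are
  NCV, never errors; per-gene model failures are recorded as
  `nonconverged` and never abort a scan.
* Seeds: every simulation stage derives its own stream from the config
  seed (kept below $2^{31}$), so studies are reproducible component by
  component.

## Scaled-down testing

The unit suite runs on a desk-scale world (2 families × ~40 individuals,
100 genes, 5 causal) and a medium world (4 families, ~280 individuals)
where rare variants have room to segregate; the acceptance suite uses the
full-scale default (8 families, ~700 individuals) for heritability
recovery, LRT calibration at 1,000 null replicates, screening calibration
at 200 genes × 20 seeds, and the ~30% prevalence check. Replicate counts
in unit tests are deliberately smaller than their acceptance
counterparts; both state their tolerances in the test files.

## Known limitations

* Observed-scale analysis of a binary trait; no liability-scale
  correction, no ascertainment modeling.
* Approach D's selection rule is an interpretation of an ambiguous
  published criterion (see above).
* The variance-component association tests use pedigree-expected
  relatedness, not marker-estimated or gene-specific IBD.
* Two-point/multipoint linkage, database retrieval (LD panels, pathway
  downloads) and descriptive cohort regressions of the source study are
  out of scope; pathways enter as GMT files.
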