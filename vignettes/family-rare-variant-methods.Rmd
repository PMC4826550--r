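---
title: "Family-based rare-variant association for healthy-aging phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The problem famvar addresses

Cohorts of long-lived families — sibships selected for exceptional
survival, their married-in spouses as unrelated controls, and their
offspring — are a powerful design for finding rare, pedigree-specific
variants that influence healthy-aging phenotypes. Analyzing them requires
machinery that ordinary GWAS pipelines lack: kinship-aware mixed models,
Mendelian-consistency quality control, reference-population scoring of
traits that are exceptional *by construction* in such a cohort, and
rare-variant tests whose null distributions respect family correlation.
famvar implements that pipeline end to end, together with a synthetic-data
generator so every stage is testable without access-controlled study data.

## Pedigree kinship

`kinship()` uses the recursive tabular method, processing each family in
generation order:

$$\varphi_{ii} = \tfrac12\bigl(1 + \varphi_{f_i m_i}\bigr), \qquad
  \varphi_{ij} = \tfrac12\bigl(\varphi_{f_i j} + \varphi_{m_i j}\bigr),$$

with founders mutually unrelated and a missing parent treated as an
unrelated founder. This is exact and $O(n^2)$ per family, which is the
right trade-off for study-sized pedigrees (tens of members); path-counting
is never needed. The additive relationship matrix $2\Phi$ is block
diagonal by family, and `kinship_eigen()` exploits that: eigendecomposing
per block makes the mixed-model machinery linear in cohort size for fixed
family size, and one decomposition is reused across every variant,
permutation and replicate for a given phenotype. X-linked inheritance is
not modeled; all sites are treated as autosomal.

Correctness is checked two ways: textbook identities (parent–offspring
0.25, first cousins 0.0625, child of first cousins has self-kinship
$0.5(1+1/16)$), and a gene-dropping Monte Carlo oracle — drop a locus with
globally unique founder alleles $10^5$ times and count identity-by-descent
— which must agree within three standard errors for every pair.

## Mendelian-inconsistency QC and the filter cascade

A trio is flagged only when the child's genotype is *impossible* under
biallelic autosomal transmission (hom-ref child with a hom-alt parent,
hom-alt child with a hom-ref parent, heterozygous child of two identical
homozygotes). Trios with any missing member genotype are skipped rather
than imputed: the paper trail for a Mendel filter should never contain
phantom errors, so the conservative choice is deliberate. Duplicate trios
are rejected at load time.

`apply_filters()` applies the cascade in its printed order — mean coverage
< 5×, quality < 45, call rate < 60 % (all strict inequalities, so a
variant exactly at a threshold survives), then the MAF-stratified
Mendel-error rule, and in burden mode additionally MAF > 1 % and
non-functional class. The Mendel rule excludes a variant when errors occur
in at least 3 families for MAF < 0.01, then ≥ 7, 12, 26, 30, 32, 38 for
the successive bins up to 0.51; the lowest bin's "more than 2 pedigrees"
is read as "3 or more", the only reading consistent with the other bins.
The retained set is order-invariant; only the removal log's attribution
(first failing filter) depends on order. "Non-functional" means intronic
and intergenic: burden tests keep exonic, UTR, splicing and non-coding-RNA
classes. MAF for filtering is computed over all genotyped subjects;
whether spouses should be excluded is configurable but not defaulted,
since the source protocol does not specify.

## Derived phenotypes

* **Healthy Aging Index**: each of systolic blood pressure, forced vital
  capacity, MMSE, creatinine and fasting glucose is scored 0/1/2 by
  tertile (0 = healthiest) and summed to 0–10. "Approximate age-adjusted
  tertiles" are implemented as tertiles of residuals from a linear age
  adjustment within sex (raw-value tertiles are the config alternative).
  Unhealthy directions (higher SBP/creatinine/glucose, lower FVC/MMSE) are
  hard-coded with an override. Boundary values take the healthier score —
  a deterministic, documented tie-break. A missing component gives a
  missing index, never a partial sum.
* **Mortality-weighted HAI** multiplies the five scores by Cox-regression
  weights (0.17085, 0.38386, 0.42873, 0.13397, 0.23880) and sums.
* **Telomere length** from the qPCR T/S ratio: $bp = 1585 \cdot T/S +
  3582$.
* **Friedewald LDL** = total cholesterol − HDL − triglycerides/5, defined
  only below 400 mg/dL triglycerides; **BMI**, **pulse pressure** and
  **type-2-diabetes status** (medication use or fasting glucose ≥ 126
  mg/dL) are direct.
* **Inverse-normal transform**: rank-based with the Blom offset,
  $\Phi^{-1}\!\bigl((r - 3/8)/(n + 1/4)\bigr)$.
* **Covariate adjustment**: full-model or forward-stepwise (entry at
  p < 0.05 — the protocol names "stepwise" without parameters, so the
  conventional threshold is used) least-squares residualization,
  standardized to unit variance.

## Trait exceptionality scores

Against a matched reference population, exceptionality is the negative
logarithm of a tail probability (natural log by default, base 10 via
`log_base`):

* **Survival**: $-\log\bigl(S(\text{age})/S(40)\bigr)$ from the sex- and
  birth-cohort-matched life table, conditional on reaching age 40, with
  $S$ linearly interpolated on the table's age grid. Ages below 40 are an
  error, not a zero.
* **Quantitative traits**: one-sided tail probability in the beneficial
  direction (a two-sided option exists but is off by default, matching the
  interpretation that higher scores mean better health).
* **Disease onset**: probability of onset at the observed age *or later* —
  later onset is more exceptional; unaffected individuals get a missing
  score, never zero.

Empirical tail probabilities use $p = \max(k/n,\; 1/(n+1))$: the plain
counting estimator floored so that an observation beyond the entire
reference sample scores $-\log\frac{1}{n+1}$ rather than infinity. (The
floor, rather than a global $(k+1)/(n+1)$ shift, keeps the boundary cases
exact: onset at the reference minimum has $p = 1$ and score 0.) Because
$-\log p$ of a uniform $p$ is Exponential, the score distribution under a
null reference is testable by Kolmogorov–Smirnov, and is.

Linear interpolation of $S$ makes scores grid-robust to roughly $10^{-3}$
for Gompertz-shaped tables at ages up to the early 80s; beyond ~90 the
hazard curvature within 1-year grid cells grows, and a finer grid (or
single-year official tables) is advisable.

## The kinship linear mixed model

Single-variant association fits
$$y = X\beta + g\gamma + u + \varepsilon,\qquad
  u \sim N(0,\, 2\Phi\,\sigma^2_g),\quad
  \varepsilon \sim N(0,\, I\,\sigma^2_e).$$
After rotating by the eigenvectors of $2\Phi$ the covariance is diagonal
in the heritability ratio $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$,
so the variance profile is one-dimensional: a 21-point grid over $[0, 1)$
followed by local refinement (`optimize`) guarantees the reported optimum
is at least as good as every grid point — unimodality is not assumed.
REML is the default; the collapsed burden test uses ML, following the
source protocol's explicit statement there. Effects are tested by a Wald
$z$ against the normal reference (the mixed-model convention at cohort
sizes in the thousands). Missing genotypes drop the individual for that
variant (complete-case per variant). Fitted with $h^2$ fixed at 0 the
model reproduces ordinary least squares exactly, which anchors the
implementation to `lm()` in tests.

Reporting conventions follow the study: genomic control $\lambda$ is the
*median observed p over median expected p* (0.5) — reported, never used to
correct p-values; Bonferroni thresholds divide 0.05 by the number of
variants (not phenotypes); and Wald results with fewer than 10 minor
allele copies are partitioned as "unstable" (the boundary MAC = 10 goes to
the stable set, since the printed split of "more than 10" vs "less than
10" leaves it unassigned).

## Rare-variant burden and kernel tests

For each gene's post-QC rare functional variants $G$ ($n \times m$):

* **UWSS**: row sums of $G$, missing dosages imputed to twice the MAF.
* **WSS**: Madsen–Browning weights from control (married-in spouse) allele
  frequencies with add-one smoothing, $w_j = 1/\sqrt{n_c q_j (1-q_j)}$,
  $q_j = (m_j+1)/(2n_c+2)$; an explicit `use_all` flag falls back to
  all-sample frequencies when controls are unavailable.
* Both scores are tested as a single fixed predictor in the kinship LMM
  with ML variance components and a Wald test.
* **famSKAT-style kernel test**: with the null model's
  $\hat V = 2\Phi\hat\sigma^2_g + I\hat\sigma^2_e$ and residuals $r$,
  $$Q = r^\top \hat V^{-1} G W^2 G^\top \hat V^{-1} r,$$
  with $W = \mathrm{diag}\,\mathrm{Beta}(\mathrm{maf}; 1, 25)$ density
  weights by default (flat optional). $Q$ follows a mixture of
  $\chi^2_1$ with the eigenvalues of $W G^\top P G W$, $P = \hat V^{-1} -
  \hat V^{-1}X(X^\top \hat V^{-1}X)^{-1}X^\top \hat V^{-1}$. With identity
  relatedness this collapses to standard SKAT, which an independent
  from-scratch oracle verifies to $10^{-6}$.
* **PWST-style adaptive test**: per-variant score tests under the null LMM
  give $p_j$ and effect signs $s_j$; adaptive weights $a_j = s_j \cdot
  (-\log_{10} p_j)$ define a burden score whose Wald $z^2$ is calibrated
  by permutation. Family correlation is handled by decorrelating the
  residuals through the Cholesky factor of $\hat V$, permuting,
  re-correlating — and re-estimating the adaptive weights in every
  permutation, so the overfitting of data-derived weights is reproduced
  under the null rather than inflating type I error. The published method
  description does not fix these internals; the signed $-\log_{10} p$
  weight, the decorrelate-then-permute scheme and per-permutation
  re-estimation are this package's documented interpretation, each
  switchable (`decorrelate = FALSE` permutes raw residuals). Permutation
  p-values are $(1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$,
  bounded below by $1/(n_{perm}+1)$, and bit-reproducible given a seed.

Gene scans tier results at 0.05 / (number of genes) for significance and a
fixed $10^{-3}$ as suggestive, and report genes with fewer than two
polymorphic post-filter variants as skipped rather than tested.

### Mixture-of-chi-squares tail probabilities

`pchisqsum()` evaluates $P(\sum_i \lambda_i \chi^2_1 > q)$ by numerical
inversion of the characteristic function (Imhof's formula). The integrand
$\sin\theta(u)/(u\rho(u))$ oscillates no faster than $(\sum\lambda + q)/2$,
so it is integrated by Gauss–Legendre panels an eighth of a period wide
out to a cutoff where the alternating tail is bounded below $10^{-9}$ by
the envelope $1/(u\rho(u))$; against a tight-tolerance adaptive reference
the error is below $10^{-9}$ across random spectra. A single eigenvalue is
handled in closed form; near-degenerate spectra whose envelope decays too
slowly fall back to the Kuonen saddlepoint and, as a last resort, a
Satterthwaite moment match — the method used is recorded in the result.

## The synthetic world

`sim_dataset()` states the world the test suite measures:

* **Pedigrees** (default 50 families): a proband sibship of $2 +
  \mathrm{Pois}(1)$ (paper-scale families), each sib married to a founder
  spouse with $1 + \mathrm{Pois}(1)$ offspring; the sibship's parents are
  recorded in the pedigree (so sib-sharing is encoded) but not genotyped,
  as the grandparent generation is deceased in such cohorts. Average
  genotyped family size ≈ 10.
* **Genotypes**: founder alleles from a spectrum of 55 %
  pedigree-private singletons (one founder heterozygote), 35 % rare
  (MAF $0.0005 + 0.0095\,\mathrm{Beta}(1,3)$) and 10 % common
  (U(0.01, 0.3)); descendants by gene dropping (each parental allele
  transmitted with probability ½). Default 100 genes with $2 +
  \mathrm{Pois}(10)$ variants each — a desk-scale stand-in for the
  study's ~69 analyzed variants per gene. Sites are unlinked: no LD, no
  coalescent history, which is deliberate (pedigree consistency is the
  requirement, population history is not).
* **Phenotypes**: $y = G\beta + u + \varepsilon$ with
  $u \sim N(0, 2\Phi\sigma^2_g)$ drawn through per-family Cholesky
  factors; default $h^2 = 0.3$. The spiked causal gene's effects sit on
  its *rare functional* variants at 2 phenotype SD per allele —
  conservative relative to the 3.5–5 SD effects the motivating study
  printed for its detected rare variants. At these defaults the causal
  gene attains the smallest famSKAT p in effectively all replicates
  (100 % over 25 calibration seeds), which is what the end-to-end
  detection test certifies at the ≥ 80 % level.
* **Life tables**: Gompertz $S(t) = \exp(-(a/b)(e^{bt}-1))$ with $b =
  0.09$ and $a = 6\times10^{-5}$ (men) / $4\times10^{-5}$ (women), modal
  ages at death ≈ 81/86.
* **Artifacts**: genotype missingness, low-coverage/low-quality variants,
  capture gaps (call rate forced below threshold), and Mendel errors
  injected by corrupting a child genotype in chosen families — all
  recorded as ground truth.

What the generator does **not** emulate — and hence what a green test does
not establish: linkage disequilibrium and haplotype structure, incomplete
relative sampling (which is why the study's 46 % singleton share among
rare variants exceeds the generator's ~20 %: fully genotyped sibships
observe transmitted copies that real sampling misses), genotyping error
other than the injected classes, population stratification, and real
secular trends in the life tables.

## Numerical choices and limitations

* Kinship eigendecomposition tolerates eigenvalues down to $-10^{-8}$
  relative before declaring the matrix non-PSD; negative dust is clamped
  to zero.
* The heritability profile is searched on $[0, 0.999]$; $h^2 = 1$
  (singular residual) is excluded.
* Permutation seeds are saved and restored around every stochastic test,
  so calling them never perturbs the caller's RNG stream.
* The Wald test is the only single-variant test offered (no score/LRT),
  and binary traits are handled through onset exceptionality scores, not
  GLMMs — both scope choices, not oversights.
* Covariate selection in stepwise mode uses marginal F-tests; with highly
  collinear candidate sets the selected subset is order-dependent, and a
  rank-deficient full design is an error naming the aliased columns.
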