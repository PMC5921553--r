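---
title: "Variance-components analysis of familial resemblance in family omics"
author: "famres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-components analysis of familial resemblance in family omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famres)
library(SummarizedExperiment)
```

## The model

In a cohort of nuclear families, the between-subject variance of an omics
feature (an expression probe, a CpG methylation level) can be partitioned
into three sources: polygenic effects transmitted from parents to children
(variance $V_g$), environment shared by members of the same household
($V_c$), and environment unique to each individual ($V_e$). For a vector of
residualized feature values $y$ over $n$ subjects, the model is

$$y \sim N\!\left(\mu\mathbf{1},\; V_g A + V_c H + V_e I\right),$$

where $A$ is the additive relationship matrix — twice the kinship
coefficient $\Phi$, computed by the standard recursion over a parents-first
ordering with founders assumed unrelated and non-inbred — and $H$ is the
household indicator (1 for subjects in the same family). The three
heritability summaries are ratios of components to the total:
*maximal heritability* $h^2_{max} = (V_g+V_c)/(V_g+V_c+V_e)$, *genetic
heritability* $h^2_g = V_g/(V_g+V_c+V_e)$ and the *common environmental
effect* $c^2 = V_c/(V_g+V_c+V_e)$, so $h^2_{max} = h^2_g + c^2$ holds
identically — the package computes the ratios from one fit, making the
identity exact to machine precision on every feature.

The *familial effect* of a feature is the joint departure of $V_g$ and $V_c$
from zero. `familialTest()` compares the full fit against the closed-form
null fit ($V_g = V_c = 0$) by likelihood ratio. The default reference
distribution is $\chi^2_2$; because both components sit on their boundary
under the null, this is conservative, and a boundary-corrected mixture
$\tfrac14\chi^2_0 + \tfrac12\chi^2_1 + \tfrac14\chi^2_2$ is available behind
`mixture = TRUE`. We default to the conservative choice because per-feature
false positives are the costlier error in a genome scan.

## Fitting: parameterization, multi-starts, boundaries

`fitVarComp()` maximizes the likelihood by Nelder–Mead on a softplus scale
for the variances (so negative values are unreachable), with the mean
profiled out analytically by generalized least squares and $V_e$ floored at
`1e-8`. Three deterministic starting points — equal split, genetic-heavy and
environment-only, all scaled to the sample variance — make the scan
bit-reproducible: no random restarts anywhere.

Boundary solutions are handled by model enumeration rather than by letting
the optimizer crawl toward $-\infty$ on the softplus scale: the nested
submodels with $V_g = 0$, $V_c = 0$, or both are fitted alongside, and the
simplest model whose likelihood ties the best within `1e-6` is returned.
This is what makes a noise feature report $h^2_{max}$ of exactly 0 (and a
genome scan under a true null shows a large point mass there), and it
guarantees the likelihood ratio against the null is never negative.

The covariance $V_g A + V_c H + V_e I$ is block diagonal by family, so the
likelihood factorizes; families with identical within-family $(A, H)$
templates share one Cholesky factorization per evaluation. This makes scans
over hundreds of replicated families no more expensive per evaluation than
the 16-family case.

One identifiability caveat worth knowing: in small families $A$ and $H$ are
strongly collinear (in a mother–child pair, only $V_g/2 + V_c$ enters the
off-diagonal), so the *split* between $V_g$ and $V_c$ is estimated much less
precisely than their sum. With component truth on the interior the means are
recovered well; with $V_c = 0$ exactly, some familial variance migrates into
$\hat V_c$ feature-by-feature while $\hat V_g + \hat V_c$ tracks the total
familial variance. The AE model (`model = "ae"`, $V_c \equiv 0$) is provided
for comparison and reports $V_g/(V_g+V_e)$.

## Bivariate genetic correlations

For a pair of features (e.g. an expression probe and a CpG site),
`geneticCorrelation()` fits the two-trait model whose cross-trait covariance
is $\rho_g\sqrt{V_{g1}V_{g2}}\,A + \rho_c\sqrt{V_{c1}V_{c2}}\,H +
\rho_e\sqrt{V_{e1}V_{e2}}\,I$. Correlations are optimized on an atanh scale
and pinned to $|\rho| \le 1 - 10^{-6}$, which keeps each component's
$2\times2$ coefficient matrix positive semidefinite and hence the whole
covariance valid. $\rho_g = 0$ is tested by likelihood ratio with one degree
of freedom ($\rho_g$ is interior under this null, so no boundary correction
is needed). Starting values are deterministic: the two univariate fits seed
the variances; the phenotypic correlation and zero seed the correlations.
When a trait has essentially no familial variance, $\rho_g$ is not
identifiable and the fit returns `NA` with a machine-readable reason instead
of failing — mirroring how bivariate screens in practice obtain genetic
correlations for only a subset of phenotypically correlated pairs.

## The phenotypic screen

`phenotypicScreen()` computes all $|A|\times|B|$ Pearson correlations
between two feature sets, with two-sided p-values from the Fisher transform
($z = \operatorname{atanh} r$, $z\sqrt{n-3}$ asymptotically standard
normal) and a Bonferroni threshold $\alpha/(|A||B|)$. The grid is processed
in row blocks so large screens stream; exact pass counts are kept for the
full grid while only pairs below a report threshold are materialized.
Zero-variance features yield undefined correlations but stay in the
multiple-testing denominator — the denominator is the designed grid, not the
testable subset.

## Preprocessing and cell-type adjustment

The expression-style detection filter keeps features whose detection p-value
is at most the threshold (default 0.05) in at least a fraction (default 25%)
of subjects, boundary inclusive. For methylation-style data the convention
in the literature is ambiguous about the inequality's direction, so
`direction` is a parameter (`"below"`, the Illumina expression convention,
is the default) rather than a hard-wired guess.

`normalizeFeatures()` applies `log2(x + 1)` followed by quantile
normalization across subjects (via `limma::normalizeQuantiles`, ties
averaged). This is deliberately a stand-in for platform-specific background
correction and variance-stabilizing transforms, which require raw array
data; it preserves within-subject rank order and equalizes the per-subject
distributions, which is the contract the downstream stages rely on.

`residualizeFeatures()` takes per-feature OLS residuals on a design of
intercept, batch and array-position indicators, sex, centered age, centered
age², sex-by-age interactions, and cell-proportion columns minus one class
(proportions sum to one; age is centered before squaring to tame
collinearity — the coefficients are nuisances and never interpreted).
Collinear columns are dropped by QR pivoting with a warning.

Cell proportions come from `estimateProportions()`: per-subject least
squares against a reference signature with nonnegativity enforced by
iteratively dropping the most negative coefficient and refitting, then
renormalizing to the simplex. This pruning scheme was chosen over quadratic
programming for transparency — every step is an ordinary least-squares fit —
and it satisfies exact noiseless recovery; a QP-based estimator would be a
drop-in extension. The package ships only *synthetic* signatures
(`makeCellSignature()`); published blood reference matrices are not
redistributed, but any user-supplied features-by-types table works.

## The simulator and what it does (not) emulate

`simulatePedigree()`'s study preset builds 16 nuclear families with 48
subjects: 16 mothers, 6 fathers, 26 children, child counts
3,3,3,2,2,2,2,1,…,1 and fathers in families 1, 2, 4, 8, 9, 10. This
composition is a reconstruction from the published totals: it yields 13
sibling pairs, 26 mother–offspring pairs, 37 parent–offspring pairs and —
when the 6 spouse pairs are pooled with unrelated pairs — 1078 unrelated
pairs out of 1128. Parent ages are uniform on 30–55 y and child ages on
8–18 y (the enrolment window), child sex Bernoulli(0.5). Children of
non-enrolled fathers carry an absent father, so siblings in those families
have kinship 0.25 (half-sib by the missing-parent convention) rather than
0.5; closed-form sibling-correlation checks therefore use fully-fathered
custom pedigrees.

`simulateFeatures()` draws features from the exact model covariance using a
symmetric eigenfactorization (so singular limits such as $V_e = 0$ are
drawable), then adds optional sex/age/batch effects;
`simulateBivariate()` extends this to trait pairs with chosen $\rho_g,
\rho_c, \rho_e$; `simulateDetection()` constructs detection p-values whose
filter outcome is known by design; `simulateMixture()` produces bulk
profiles as signature-weighted Dirichlet mixtures. Every stage takes its own
seed; `runPipeline()` derives per-stage substreams from one master seed, and
reruns are byte-identical.

What passing these tests shows is that the estimators recover the model
they assume. Real arrays add probe-level artifacts, non-Gaussian tails,
bounded methylation proportions (we simulate on an unbounded M-value-like
scale), batch structure correlated with families, and assay noise that is
not i.i.d.; none of these are emulated, so simulation performance is an
upper bound on real-data performance.

## Reference problem sizes

The validation suites use: the 16-family study composition for calibration
checks (1000 null features for LRT calibration; rejection must stay below
$0.05$ plus two binomial standard errors — the $\chi^2_2$ reference is
conservative, so observed rates near 1–2% are expected); 200 replicated
study-like families with 200 features for variance-component recovery
(means within $\pm 0.05$ of truth $(0.4, 0.2, 0.4)$); 300 families with 100
pairs for genetic-correlation recovery (mean within $\pm 0.1$ of
$\rho_g = 0.9$); dense-oracle likelihood agreement to $10^{-8}$ over 100
random draws on pedigrees of up to 12 subjects; and gene-dropping kinship
agreement to Monte-Carlo precision on random pedigrees of up to 10 members.

## A small worked run

```{r example, eval = FALSE}
ped <- simulatePedigree(seed = 1)
se <- simulateFeatures(ped, 200, vg = 0.5, vc = 0.2, ve = 0.3, seed = 2)
scan <- genomeScan(se, ped)
scanSummary(scan)
```

## Known limitations

* No dominance or epistatic components, no gene-environment interaction,
  and no genotype-based analyses (the design has no genotypes).
* Standard errors of variance components are not reported; inference is via
  the likelihood-ratio tests.
* Twin zygosity, X-linked kinship and inbred-pedigree dominance matrices
  are out of scope; founders are always treated as unrelated.
* The $\chi^2_2$ familial test is conservative; the mixture option is
  provided but shares the usual caveat that the true boundary mixture
  weights depend on the design.
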