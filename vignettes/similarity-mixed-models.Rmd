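---
title: "Similarity-aware mixed models for log2 fold changes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-aware mixed models for log2 fold changes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfcmm)
```

## The model

`lfcmm` fits a single-random-effect mixed linear model to a vector of
per-transcript log2 fold changes:

$$\mathbf{y} = \mu\mathbf{1} + \mathbf{Z}\mathbf{x} + \mathbf{e},
\qquad \mathbf{x} \sim N(\mathbf{0}, \mathbf{V}\sigma^2_x),
\qquad \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e).$$

The response is the log2FC itself, not counts: upstream quantification and
shrinkage (e.g. Salmon + DESeq2) are assumed done. The model's leverage
comes from $\mathbf{V}$, which encodes how similar two random-effect levels
are; the fit shares information between similar levels and shrinks all
effects toward zero. Four configurations of (levels, $\mathbf{V}$) are
supported:

* **transcripts** with exon-composition similarity (per-gene blocks),
* **genes** with the identity (independence),
* **GO terms** with the Jaccard coefficient of their gene sets,
* **Reactome pathways**, likewise Jaccard.

Assumptions worth stating: a single global mean (no further fixed effects);
homoscedastic residuals; one random effect per fit (variants are fitted
separately, not jointly); and a known, fixed $\mathbf{V}$ — uncertainty in
the annotation is not propagated.

## Covariance construction

**Exon similarity.** For transcripts $i, j$ of one gene, entry
$(i,j) = a/N$ with $a$ the number of exons shared and $N$ the gene's number
of distinct exons (the size of the union of its transcripts' exon sets).
Exon identity is exact coordinate equality — tuple (chromosome, start, end,
strand) in 1-based inclusive GTF coordinates — which is deterministic and
matches how Ensembl emits exon records. The formula is applied literally
*including the diagonal*: entry $(i,i) = |E_i|/N < 1$ for a transcript that
skips exons. This is a deliberate design choice: with that diagonal the
matrix equals $(1/N)\,\mathbf{M}\mathbf{M}'$ for the transcript-by-exon
membership matrix $\mathbf{M}$ and is therefore a Gram matrix, positive
semidefinite by construction. A `correlation_scale` option rescales to unit
diagonal for users who prefer a correlation form. Independence across genes
makes the full $\mathbf{V}$ block-diagonal, which the solver exploits.

**Term overlap.** For two terms with gene sets $A, B$ the entry is
$J(A,B) = |A\cap B|/|A\cup B|$, diagonal exactly 1. Jaccard matrices over
overlapping set systems are *not* guaranteed positive semidefinite, so
`ensure_psd()` clips negative eigenvalues (floor 0 by default),
reconstructs, re-symmetrizes and restores the unit diagonal, flagging the
repair. A PSD input is returned unchanged.

```{r psd-example}
uni <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g1", "g3"))
V <- ensure_psd(term_overlap_jaccard(uni))
min_eigenvalue(V)
```

**Singular blocks.** Two identical transcripts produce a singular exon
block. The construction is kept literal; invertibility is handled at solve
time by a ridge of `1e-8` added to a block's diagonal only when its
condition number exceeds `1e12` (reported in the result). The ridge is
applied per block; a dense fit of the same matrix would place it on the
whole diagonal, so the two paths may differ at the ridge's magnitude for
singular inputs — one reason the test suite checks path agreement on
nonsingular instances.

## Estimation

**EM-REML.** Writing $\lambda = \sigma^2_e/\sigma^2_x$, each iteration
solves Henderson's mixed model equations at the current variances and
updates

$$\sigma^2_x \leftarrow \frac{\hat{\mathbf{x}}'\mathbf{V}^{-1}\hat{\mathbf{x}}
 + \sigma^2_e\,\mathrm{tr}(\mathbf{V}^{-1}\mathbf{C}^{xx})}{q},
\qquad
\sigma^2_e \leftarrow \frac{\mathbf{y}'\mathbf{y} - \hat\mu\mathbf{1}'\mathbf{y}
 - \hat{\mathbf{x}}'\mathbf{Z}'\mathbf{y}}{n - 1},$$

with $q$ the number of levels and $\mathbf{C}^{xx}$ the random-effect block
of the inverse of the $\lambda$-scaled coefficient matrix. The residual
update divides by $n-1$ because the only fixed effect is the intercept.
Defaults: start at $\sigma^2_x = \sigma^2_e = s^2_y/2$, stop when the
maximum relative change of both components falls below `1e-8`, cap at 5000
iterations. The REML log-likelihood is recorded after every update; the
trace is non-decreasing (a property the tests verify against an
independent dense evaluation through the marginal covariance
$\mathbf{V}_y = \mathbf{Z}\mathbf{V}\mathbf{Z}'\sigma^2_x + \mathbf{I}\sigma^2_e$).

When the data carry no between-level signal the EM sequence decays toward
the $\sigma^2_x = 0$ boundary; the iteration stops early (boundary treated
as converged) once $\sigma^2_x$ falls below $10^{-12}\, s^2_y$, and a
constant response returns the zero-variance boundary directly. EM is
first-order and slows near the boundary, so null fits may also end by the
iteration cap with an honest `converged = FALSE` flag; the standardized
tests are unaffected because they only use the solution vector up to scale.

**Solver.** The package never forms $n \times n$ matrices during fitting.
A one-time preparation finds $\mathbf{T}$ with
$\mathbf{V} = \mathbf{T}\mathbf{T}'$ and
$\mathbf{T}'\mathbf{Z}'\mathbf{Z}\mathbf{T} = \mathrm{diag}(\theta)$
(simultaneous diagonalization via one eigendecomposition of $\mathbf{V}$
and one of $\mathbf{L}'\mathbf{Z}'\mathbf{Z}\mathbf{L}$), after which every
EM iteration is $O(q)$ vector arithmetic in
$w_i = 1/(\theta_i + \lambda)$, and the intercept is folded in by a scalar
Schur complement. With a block-diagonal $\mathbf{V}$ and a conformable
$\mathbf{Z}'\mathbf{Z}$ the preparation runs per block, so the
transcript-level model scales to tens of thousands of observations on a
desktop. The dense GLS/BLUP closed forms
($\hat\mu = (\mathbf{1}'\mathbf{V}_y^{-1}\mathbf{1})^{-1}
\mathbf{1}'\mathbf{V}_y^{-1}\mathbf{y}$,
$\hat{\mathbf{x}} = \sigma^2_x\mathbf{V}\mathbf{Z}'\mathbf{V}_y^{-1}
(\mathbf{y} - \mathbf{1}\hat\mu)$) are kept in the test suite as the
independent oracle; agreement is at numerical precision (max abs diff
below 1e-8 over hundreds of random instances, typically 1e-13).

**Prediction-error variance.** The per-level PEV is
$\sigma^2_e$ times the corresponding diagonal entry of the inverse
coefficient matrix, available from the same spectral preparation; it is
reported as a diagnostic.

## Testing

Each solution element is standardized with the *empirical mean and standard
deviation of the solution vector of that fit*,
$z_k = (\hat{x}_k - \bar{\hat{x}})/\mathrm{sd}(\hat{x})$, and tested
two-sided, $p_k = 2(1 - \Phi(|z_k|))$. The alternative — dividing by the
prediction-error standard deviation per level — was considered and
rejected: empirical standardization implies one common effect-to-z ratio
across the levels of a fit, and published results of this model family show
exactly that internal consistency across their reported effect/p pairs.
A consequence worth knowing: the empirical SD makes the test *relative
within a fit* (is this level extreme among its peers), not an absolute test
of $x_k = 0$.

No multiple-testing correction is applied by default — fitting all effects
jointly with shrinkage is the model's own guard against spurious extremes —
but a `fdr = TRUE` option adds a Benjamini–Hochberg column for users who
want it.

**Variance proportions** are reported as $100\,\hat\sigma^2_x / s^2_y$ with
$s^2_y$ the unbiased sample variance of the response. The alternative
denominator $\hat\sigma^2_x + \hat\sigma^2_e$ is exposed via an argument;
the sample-variance convention was chosen because the quantity of interest
is the share of the *observed* log2FC variability.

## Annotation handling

* GTF parsing goes through `rtracklayer`; only exon features with
  `gene_id`/`transcript_id` attributes are used, and duplicate exon lines
  collapse by coordinate identity.
* Reactome mappings are gene-keyed (Ensembl2Reactome layout); transcripts
  inherit their gene's pathways through a transcript-to-gene map.
* Transcripts without annotation for a model are excluded from that model's
  response with a reported count — they contribute no estimable level.
* A transcript with $k$ terms carries $k$ ones in its incidence row;
  row-normalized weights are available via `weighted = TRUE`.
* GO hierarchy-level filtering counts levels along `is_a` edges only, root
  (`biological_process`) at level 0, using the *minimum* path length.
  Annotations to deeper terms are lifted to **all** of their level-$L$
  ancestors; shallower terms are dropped. By default **no** level filtering
  is applied: deep, specific terms are informative, and a strict collapse
  to a shallow level discards them; the filter exists for users who want
  comparable term granularity.

## The synthetic-data generator

`simulate_gene_models()` draws, per gene, an exon universe and transcripts
that include each exon independently with probability `sharing` (forced
non-empty); `simulate_term_assignments()` draws random term gene sets with
full gene coverage; `simulate_expression()` draws
$\mathbf{x} \sim N(0, \mathbf{V}\sigma^2_x)$ through an eigen square root
of $\mathbf{V}$ (negative eigenvalues clipped at 0, consistent with
`ensure_psd`) and adds i.i.d. residuals. Defaults mimic a desk-scale
transcriptome: ~700 genes with 1–6 transcripts and 3–12 exons each,
`sharing = 0.7`, 100 GO-like and 80 pathway-like terms, and a
random-effect share of about 15% of the response variance — the order of
magnitude seen for transcript-level effects in heat-stress transcriptome
studies of this kind.

What the generator deliberately does **not** emulate: read counts and
their mean–variance relation, library-size effects, the shrinkage DESeq2
applies to log2FC estimates, correlated residuals, and realistic GO DAG
topology (term gene sets are exchangeable random sets). Passing tests
therefore demonstrate that the estimation and testing machinery is correct
*under the model's own assumptions*; they do not validate the biological
fidelity of those assumptions for any particular real data set.

Note one property of the exon-similarity construction under low `sharing`:
because $N$ is the union of the gene's realized exons, near-disjoint
transcripts still show non-negligible similarity when the union is small —
off-diagonals shrink with `sharing` but do not vanish at the rate a fixed
denominator would give.

## Verification choices and problem sizes

The test suite pins down each stage with an independent oracle: brute-force
membership-matrix Gram construction for exon similarity; dense GLS/BLUP
closed forms for the solver (200 random instances, $n \le 50$); a
derivative-free Nelder–Mead maximization of the dense REML log-likelihood
for the EM fixed point (20 instances, $n$ 200–400, $q$ 20–30 — sized so the
REML optimum is interior, since at the $\sigma^2_x = 0$ boundary a relative
comparison of two maximizers is ill-posed); Monte-Carlo moment checks for
the generator; and byte-identity for end-to-end determinism.

Two calibration-style checks deserve their design rationale:

* **Parameter recovery** uses ~5000 transcripts from ~1700 simulated genes
  under the transcript model, with $\sigma^2_e$ chosen so the expected
  random-effect share of $\mathrm{var}(y)$ equals the target (0.05, 0.15,
  0.30); the mean estimate over 20 seeds falls within ±0.03 of the truth.
  Identifiability here comes only from $\mathbf{V}$'s deviation from the
  identity, so single-seed estimates scatter with SD ≈ 0.02–0.04.
* **Null calibration** ($\sigma^2_x = 0$) is asserted under the gene-level
  configuration — 1000 genes × 3 transcripts, identity covariance — where
  the standardized solutions are exchangeable and the p-values should be
  (and are) uniform. Under the exon-similarity covariance the BLUPs of a
  gene's transcripts are correlated and their marginal scales differ with
  block structure, which inflates the Kolmogorov–Smirnov distance from
  uniformity; that looser behaviour is a property of the method, not a
  bug, and is why the strict bound is asserted where the model's own null
  is exchangeable.

Similarly, the BLUP-versus-truth rank correlation exceeds 0.8 only when
levels pool several observations (gene-level structure): under the
transcript model with $\mathbf{Z} = \mathbf{I}$ the correlation is capped
at $\sqrt{\text{signal fraction}}$ (≈ 0.71 at one half), a useful reminder
of how much single-observation BLUPs can know.

## Limitations

* One random effect per fit; no covariates beyond the intercept; no joint
  multi-component model.
* The empirical-SD test is relative within a fit and its null calibration
  degrades gracefully (but measurably) under strongly structured
  $\mathbf{V}$.
* Annotation quality bounds the functional models: genes without GO or
  Reactome membership drop out of M3/M4, and sparsely annotated genomes
  would leave those fits thin.
* EM-REML is first-order; near-boundary fits converge slowly and are
  flagged rather than accelerated.
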