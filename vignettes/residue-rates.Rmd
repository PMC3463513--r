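---
title: "Residue-level dN/dS versus solvent accessibility: models and methods"
author: "rsaRates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level dN/dS versus solvent accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsaRates)
```

## The scientific question

Buried residues of a protein evolve more slowly than exposed ones, and the
relationship between a residue's selective constraint — measured by the
nonsynonymous/synonymous rate ratio dN/dS — and its relative solvent
accessibility (RSA) is close to linear. `rsaRates` implements a
residue-level analysis of how two whole-protein covariates shape that line:

* **core size** — a protein's average residue RSA; large-core proteins
  (low average RSA) have proportionally more buried residues, and their
  surface residues evolve faster, steepening the slope while leaving the
  intercept (fully buried residues) nearly unchanged;
* **expression level** — highly expressed proteins are uniformly more
  constrained across *all* RSA values, which lowers both intercept and
  slope; expression additionally reduces the synonymous rate dS through
  selection on codon usage.

The discriminating statistic is the *fold change* curve: the per-RSA-bin
ratio of rates between two protein groups. A fold-change intercept
different from 1 indicates a uniform, structure-independent effect; a
nonzero fold-change slope indicates a structure-dependent one.

## Pipeline

1. **RSA annotation** (`computeSasa`, `normalizeRsa`, `transferRsa`).
   Solvent-accessible surface area is computed by Shrake–Rupley sphere
   sampling over heavy atoms (960 deterministic golden-spiral points per
   atom, probe radius 1.4 Å, Bondi van der Waals radii). Raw SASA is
   normalised to the 99th percentile within each residue type and expressed
   as a percentage; values above the normaliser are outliers set to exactly
   100%. RSA computed on a template structure is transferred to the target
   protein through an explicit residue alignment map: site-specific RSA
   depends mostly on backbone conformation, so it is well conserved between
   close homologs. Unmapped positions carry an explicit missing marker
   (`NA`), distinct from 0, because RSA = 0 is a meaningful value (fully
   buried).
2. **Binning** (`mapCodonsToStructure`, `assignGroups`, `binResidues`,
   `concatenateBinAlignment`). Codon columns of a four-taxon in-frame
   alignment are joined 1:1 to target residues. A column enters the
   analysis only if it is *gapless*: no gap, ambiguity character or stop
   codon in any taxon, and a non-missing RSA. Proteins are ranked by
   average RSA and by the expression proxy independently; the bottom and
   top `floor(fraction * N)` form the extreme groups (fraction 1/3 by
   default; 1/2 and 1/4 reproduce the coarser and finer groupings). Within
   each group, gapless residues are binned by RSA (ten 10% bins by
   default; intervals half-open, last closed) and each bin's codon columns
   are concatenated, sorted by protein then residue for determinism.
3. **Rate estimation** (`estimateRatesML`, `bootstrapSE`). Each bin's
   concatenated alignment is analysed under a single-ratio Goldman–Yang
   codon model on a fixed unrooted four-taxon topology: 61 sense-codon
   states, rate proportional to the target codon frequency, times kappa
   for transitions, times omega for nonsynonymous changes, scaled to one
   expected substitution per codon per unit branch length. Codon
   frequencies follow the F3x4 convention (position-specific nucleotide
   frequencies, +1 pseudocount per nucleotide). Omega, kappa and all five
   branch lengths are optimised jointly. Standard errors come from a
   codon-column bootstrap: resample columns with replacement, re-estimate,
   and take the standard deviation over replicates (100 replicates by
   default).
4. **Regression** (`weightedLineFit`, `compareLineParams`,
   `testParamNull`, `foldChangeCurve`). Per-bin estimates are fitted with
   the standard error-weighted straight line (chi-square minimisation with
   known per-point sigma; closed-form normal-equation sums give the
   parameter standard errors). Slopes/intercepts of two lines are compared
   with t = (a − b)/sqrt(se_a² + se_b²) on n₁ + n₂ − 4 degrees of freedom;
   a single parameter is tested against a null value on n − 2 degrees of
   freedom. Fold-change curves divide two groups' per-bin estimates, with
   delta-method errors, and are themselves fitted and tested against the
   no-effect nulls (slope 0, intercept 1). P-values are reported
   unadjusted; no multiple-testing correction is applied.

`runPipeline()` chains these stages from a single seeded configuration and
emits audit TSVs plus a JSON manifest of output checksums; re-running with
the same configuration and seed reproduces every output byte-for-byte.

## The synthetic study generator

Because the real structural/ortholog dataset is not redistributed with the
package, `simulateStudy()` generates a fully specified study with known
ground truth, which is what the test-suite exercises end to end:

* four group-cells (core size × expression), 50 proteins per cell and
  120–180 residues per protein by default;
* per-residue RSA from class-specific Beta distributions scaled to
  [0, 100] — Beta(1.2, 2.6) for large-core (mean ≈ 32%) and Beta(2.0, 1.9)
  for small-core (mean ≈ 51%) — so class labels are recoverable from
  average RSA but the distributions overlap realistically;
* per-residue omega (the observable dN/dS) linear in RSA,
  `omega = f_e * (b + m_c * RSA)` with floor 0.01: intercept b = 0.07,
  slope 0.0004/% for small-core and 0.0034/% for large-core proteins
  (core size modulates slope only), and a uniform factor f_e = 2.6 for
  low-expression proteins (expression scales the whole line). These
  defaults put omega between ~0.07 (buried, high expression) and ~1
  (exposed residues of large-core low-expression proteins), a realistic
  purifying-selection range with visibly different slopes between cells.
  The small-core slope is kept small relative to the intercept so that
  the large-core/small-core *fold-change* curve — a ratio of two lines —
  stays close to linear with intercept near 1 over the observed RSA
  range; a large shared-slope component would make that ratio visibly
  concave and its linear fit would no longer start at 1;
* codon usage: uniform amino-acid composition; within each synonymous
  family one fixed preferred codon carries weight 1 + bias, with bias 0.5
  (low expression) versus 4 (high expression), so the generator's own
  adaptiveness table (preferred w = 1, unpreferred w = 0.25) separates the
  classes by CAI;
* synonymous-rate scale 1.0 (low expression) versus 0.6 (high
  expression), a uniform structure-independent dS reduction modelling
  selection on synonymous codons in highly expressed genes — a
  phenomenological rate scale, not an explicit mutation–selection model.
  The scale multiplies the whole rate matrix (with omega applied on top
  of it to nonsynonymous changes), so a site's omega parameter *is* the
  dN/dS ratio an estimator observes, and the scale shows up only in dS
  and dN, not in their ratio;
* evolution along the fixed tree
  `((cerevisiae, paradoxus), mikatae, bayanus)` with branch lengths
  0.08–0.20 expected substitutions per codon, by exact CTMC (Gillespie)
  simulation per site. Branch-length units are expected substitutions per
  codon under the *neutral* (omega = 1, scale 1) matrix of the same codon
  frequencies, so site-specific selection changes substitution counts, not
  the clock; the expression proxy is the CAI of the simulated first-taxon
  sequence under the generator's own table, closing the loop between the
  generator and the codon-bias module.

What the generator deliberately does **not** emulate: indels (the pipeline
consumes gapless columns only), among-protein tree-length variation,
site-to-site rate autocorrelation, template/target RSA annotation error,
and any mechanistic model of misfolding or mis-interaction. Passing tests
therefore demonstrate that the pipeline recovers the generative structure
it targets, not that real data are free of these complications.

## Numerical choices

* **Transition probabilities** are applied by uniformization (a
  Poisson-weighted power series in the sparse rate matrix) rather than by
  dense eigendecomposition; every sense codon has at most nine
  single-nucleotide neighbours, which makes this both exact and fast at
  the short branch lengths involved. The series runs to machine convergence for direct
  likelihood evaluation (`treeLogLikelihood`) and is truncated at an
  accumulated Poisson mass of 1 − 3e−10 inside the optimiser.
* **Optimisation** is box-constrained quasi-Newton on log-transformed
  parameters with analytic branch-length gradients (one pre-order pass)
  and forward-difference gradients for kappa and omega; three omega
  starts (0.1, 0.5, 1.5) guard against local optima. Bounds: kappa in
  [0.1, 50], omega in [1e-4, 30], branch lengths in [1e-7, 5]. The fast
  L-BFGS-B driver occasionally aborts its first line search on
  large-gradient instances and returns its starting point; that signature
  is detected and the fit is redone with the slower, very robust PORT
  routine (\code{nlminb}).
* **Codon frequencies**: F3x4 is the conventional default; when codon
  usage differs strongly between the protein groups being compared (as it
  does between the generator's expression classes), F3x4's factorisation
  error biases omega differently per group, and the empirical-61
  (\code{piMethod = "empirical"}) option is the appropriate setting — the
  four-cell analyses in the test suite use it.
* **Degenerate estimates**: an omega estimate outside [1.5e−3, 27] (in
  practice, a bin with no observed nonsynonymous or hardly any synonymous
  variation) is flagged; its bootstrap SE would be degenerate, so such
  bins are excluded from line fits and logged, as are bins where more than
  half the bootstrap replicates are undefined or the replicate spread is
  exactly zero.
* **Bootstrap refits** re-estimate omega, kappa and one overall tree-scale
  factor per replicate, holding branch-length *proportions* at the
  full-data MLE (`refit = "scale"`, the default; `refit = "full"`
  re-optimises every branch). Proportions are essentially uninformative
  for the spread of omega under column resampling, and the reduced refit
  is several-fold faster; the bootstrap-calibration test in the suite
  compares exactly this mode against the empirical sampling spread.
* **Undefined ratios**: dS = 0 makes dN/dS undefined; such estimates are
  excluded from regression with a logged warning rather than imputed.
* **Ties** in protein ranking are broken lexicographically by protein ID
  and counted; bin x-values are the mean member RSA by default (interval
  midpoints optional).

## Problem sizes used by the test suite

The automated checks run the whole machinery at desk scale on a single
core: estimator
recovery uses 2000-codon alignments; bootstrap calibration uses 50
replicate simulations at 2000 codons with 40-replicate bootstraps; the
type-I-error study of the slope-equality test uses 500 null pipeline runs
with two groups of twelve ~60-codon RSA bins and 10-replicate bootstraps;
and the four-cell analysis uses ten seeded runs at 36 proteins per cell
with eight bins and 10-replicate bootstraps. These are the package's own
reduced study conditions; the defaults of `runConfig()` (ten bins, 100
bootstrap replicates, tertile grouping) remain the recommended settings
for real analyses.

## Known limitations

* Absolute dN and dS values depend on the mutational-opportunity site
  counting convention (computed here from the neutral matrix,
  codeml-style); ratios and fold changes are robust to this choice,
  absolute magnitudes are not.
* The per-bin estimator assumes a single omega per bin; within-bin
  heterogeneity biases the estimate towards a flux-weighted average,
  which is exactly what the binned-line analysis intends but is worth
  remembering when bins are wide.
* The two-step procedure (fit lines, then compare parameters) was chosen
  for conceptual simplicity over a joint likelihood-ratio formulation;
  with known per-point errors the two are asymptotically equivalent, and
  the t-based comparison is what the fold-change machinery needs.
* CAI values depend on the reference adaptiveness table; only relative
  (fold-change) structure should be compared across analyses that used
  different tables.
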