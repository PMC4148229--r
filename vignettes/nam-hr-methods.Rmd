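---
title: "Methods: joint linkage and association mapping of HR modifiers in NAM populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint linkage and association mapping of HR modifiers in NAM populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namhr)
```

## The problem this package addresses

The hypersensitive response (HR) is a rapid, localized programmed cell
death that plants mount at the point of attempted pathogen entry. It is
too fast and too local to quantify directly in the field, so natural
variation in HR strength is studied through a reporter: an autoactive
resistance-gene allele that triggers HR lesions without any pathogen.
Crossing a tester carrying such an allele onto the lines of a nested
association mapping (NAM) panel — many biparental recombinant inbred
line (RIL) families that share one common parent — turns HR intensity
into an ordinary quantitative trait: lesion severity scored repeatedly
over a season, and mutant/wild-type ratios for height, stalk width and
flowering time.

`namhr` implements the complete analysis path for such data: trait
derivation, genotype cleaning and densification, joint multi-family
linkage mapping, and residual-based genome-wide association (GWAS) with
subagging. A synthetic NAM generator with a registered truth makes every
stage testable without any external data.

## Trait derivation

**sAUDPC.** Repeated 1–10 lesion ratings at days $t_1 < \dots < t_k$
are reduced to the standardized area under the disease progress curve,

$$\mathrm{sAUDPC} \;=\; \frac{\sum_{i=1}^{k-1}
  \tfrac{s_i + s_{i+1}}{2}\,(t_{i+1}-t_i)}{t_k - t_1},$$

a time-weighted average severity. It is invariant to shifting all
rating days, always lies within the range of the scores, and puts
seasons with 4, 5 or 6 ratings on a common footing. sAUDPC is computed
per plot per environment first and only then adjusted across
environments, matching the order in which the field design generates
the data.

**Ratio traits.** Height, stalk-width and days-to-anthesis ratios are
the mutant class mean divided by the wild-type class mean within each
F1 family (three representative plants per class in the original
design).

**Line means and heritability.** Least-squares line means adjust for
environment and family-by-environment terms by ordinary least squares;
on balanced data they reduce exactly to raw line means. Variance
components come from the expected mean squares of the line × environment
ANOVA with all factors random, computed directly from cell means (exact
on balanced data and O(N), where a naive `aov()` call would materialise
a design matrix with one column per line × environment cell). Line-mean
heritability is

$$H^2 = \frac{\sigma^2_L}{\sigma^2_L + \sigma^2_{LE}/n_E +
  \sigma^2_e/(n_E n_R)}.$$

With a single replicate per environment (the original field design)
$\sigma^2_{LE}$ and $\sigma^2_e$ are confounded; the estimator then
returns their sum in the line × environment slot with a flag, which
leaves $H^2$ itself exact. The original analysis used REML mixed models
in commercial software; fixed-effects least squares and
method-of-moments components are used here because they are
deterministic, dependency-free, and exact on the balanced and
near-balanced designs this package targets. For badly unbalanced data
they are an approximation, and that is a documented limitation.

**Correlations.** Trait–trait correlations treat the family (NAM
sub-population) as a covariate: both traits are centred within family
and the Pearson correlation of the residuals is tested on $n - g - 1$
degrees of freedom. For sign consistency across traits the lesion scale
can be inverted as $11 - x$ on the 1–10 scale; any affine inversion
changes only the sign of correlations, never the magnitude. Correlations
between founder allele-effect estimates of two traits at shared QTL are
computed over all founder-by-QTL cells.

## Genotype processing

**Parent-of-origin correction.** Low-coverage genotyping-by-sequencing
leaves many sites missing and scores most heterozygous sites as
homozygotes. Calls are re-decoded per line and chromosome under a
three-state hidden Markov model (reference homozygote, heterozygote,
alternate homozygote). Emissions: a homozygous state yields the correct
call with probability $1-\varepsilon$ and either wrong call with
$\varepsilon/2$; a heterozygous state drops out to a homozygous call
with probability $\delta$ (split evenly). Defaults
$\varepsilon = 0.005$ and $\delta = 0.8$ reflect the reported dropout
level of roughly 0.5× coverage data and are configurable — the source
analysis states only the ~80% dropout figure. Transitions follow the
Haldane recombination fraction $r(d) = \tfrac12(1-e^{-2d/100})$ of the
inter-marker distance $d$ (cM); heterozygous tracts persist with
probability $(1-r)^{2s}$ for selfing depth $s$ and are entered so the
stationary heterozygote frequency is $2^{-s}$. Decoding is the Viterbi
algorithm in the log domain; missing calls emit likelihood 1 in every
state; backtracking ties are broken toward staying in the same state so
output is deterministic and smooth. The test suite checks the decoder
against exhaustive path enumeration on hundreds of short random
instances.

**Grid imputation.** Corrected states are expanded onto a uniform grid
(default 0.2 cM, starting at 0 on each chromosome) as expected dosage of
the non-reference allele: 0 or 2 inside homozygous tracts, linear
interpolation in genetic distance between markers of different parental
origin, nearest-marker dosage beyond the terminal markers. Restricting
the grid to marker positions reproduces the input exactly.

**Projection of dense founder variants.** A dense variant known only in
the founders is projected onto a RIL from the two mapped markers
physically flanking it:

$$\hat g = \frac{d_2 G_1 + d_1 G_2}{d_1 + d_2},$$

where $d_1, d_2$ are physical distances to the left and right flanking
markers and $G_1, G_2$ the RIL's dosages there. If the family's founder
carries the reference allele at the variant the projection is 0
regardless of the flanks; a heterozygous founder call contributes allele
content 0.5 and halves the projection (the source is silent on this
case; it is flagged in the reader). Variants at exactly a mapped
marker's position take that marker's dosage; variants outside the mapped
span use the nearest marker alone. The weight assignment pairs $G_1$
with $d_2$: the closer the variant sits to a marker, the more that
marker's genotype dominates. Projection is linear in $(G_1, G_2)$,
bounded in $[0,2]$, and collapses to $G_1$ as $d_1 \to 0$.

## Joint multi-family linkage mapping

The joint model contains family main effects and marker effects nested
within families — one slope per family that segregates at the marker,
each measuring the founder allele's deviation from the common parent.
Because every term is nested in family, the design matrix is
block-diagonal: all fits decompose into per-family regressions sharing
one pooled residual variance. The implementation exploits this
throughout; it is what makes 1000-permutation thresholds and stepwise
scans tractable at thousands of lines without compiled code.

**Entry threshold.** Trait values are permuted within families
(preserving the family main-effect structure of the null model); each
permutation is scanned over all markers and its minimum p recorded; the
threshold is the $(1-\alpha)$ empirical quantile of the
$-\log_{10}(\min p)$ distribution, with $\alpha = 0.05$ and 1000
permutations in the original analysis (200 in the desk-scale tests
here). Thresholds are expressed in $-\log_{10} p$ units of the
nested-term F test; the source reports "LOD" thresholds but derives
them from minimum p values, and no LOD conversion is defined there.

**Forward selection and refinement.** At each step the marker with the
largest $-\log_{10} p$ of its nested term, given the current model,
enters if it beats the threshold (ties: smaller p, then chromosome
order, then cM). The selected model is then refined: each marker in
turn is re-fit against all markers within ±8 map-adjacent positions
(1.6 cM on a 0.2 cM grid) with the rest of the model fixed, keeping the
best; sweeps repeat to a fixed point (at most 10).

**Allele effects.** All effects are estimated simultaneously in the
final model; per-family standard errors use the pooled residual
variance. A family not segregating at a marker is reported not
estimable. Positive effects mean the non-reference allele increases the
trait.

**Support intervals.** Walking outward from a peak in map order, each
flanking marker is added to the full model and the peak's nested term is
re-tested. A nearby flank absorbs the peak's signal, so the peak term
goes non-significant; the interval boundary is the first position at
which the peak regains significance at $\alpha = 0.05$ despite the
added flank. Two other readings of the (ambiguous) published procedure
were considered and rejected during design: testing the peak against a
distant flank leaves a strong peak significant everywhere
(chromosome-wide intervals), and substituting the flank for the peak
keeps any same-chromosome marker significant when the QTL is strong
(the same degeneracy). The regain rule is the only reading that
produces bona fide support intervals — they contain the true locus, and
they shrink as the QTL effect grows, both of which are verified in the
test suite.

**Per-QTL R².** Reported as the marginal R² from dropping the marker's
nested term from the final model (the source does not define its R²
computation).

**Epistasis.** Markers are thinned to a uniform genetic spacing
(1 cM in the original, ~1400 markers) and every pair is tested with
family main effects, both markers' nested main effects, and the nested
product interaction. Pairs passing the scan threshold are added, with
their main effects, to the final additive model one at a time; the
interaction's p-value in that full model decides whether it improves on
the additive fit. Interactions use the raw dosage product; the
simulator's epistatic terms use centred dosages (Cockerham coding) so
simulated additive and epistatic variance stay orthogonal in
expectation. On purely additive simulations the full-model pass rate
stays at the nominal $\alpha$ — the calibration behind the original
finding of no significant epistatic QTL.

**Single-family scans.** A per-family one-marker regression scan with a
within-family permutation threshold is provided as a deliberately
simple stand-in for composite interval mapping, which is out of scope.
Its value is detecting family-private QTL whose signal the joint model
dilutes across 24 families.

## Residual GWAS with subagging

For each chromosome in turn, the joint model is re-fit without that
chromosome's markers (family effects retained) and the residuals become
the GWAS phenotype — dense variants are thus tested free of background
QTL on other chromosomes, and the residuals are exactly orthogonal to
every retained model column. Dense projected variants enter by forward
regression as a single across-population slope on top of family main
effects (projected dosages already encode founder origin, so a
family-nested slope would be redundant), with entry threshold
$p < 10^{-6}$.

The whole forward regression is repeated on 100 stratified subsamples
of 80% of each family's lines (without replacement, rounded down,
minimum two lines; residuals are recomputed on each subsample rather
than sliced from the full-data fit, the more conservative choice). The
resample model inclusion probability (RMIP) of a variant is the
fraction of subsamples that selected it; records above an RMIP floor of
0.05 are kept and 0.25 marks the robust-association reporting
threshold. The reported p-value is the mean $-\log_{10} p$ over the
selecting subsamples, and the effect the mean of the subsample effect
estimates (the published table note is ambiguous about the averaging
domain; this choice is documented here). The RMIP denominator is always
the full number of subsamples. Finally, associated variants within
2000 bp on a chromosome are single-linkage clustered and the member
with the highest RMIP (ties: larger mean $-\log_{10} p$, then smaller
bp) represents the cluster, reflecting the convention that such
clusters tag one causative gene.

## The synthetic NAM generator

The generator emulates the statistical structure the analysis assumes:

* a founder panel with one common reference parent fixed at allele 0
  everywhere, and dense biallelic variants whose alternate-allele
  counts among the diverse founders are drawn to land inside a target
  frequency window (0.1–0.5 by default);
* biparental RIL families in which exactly two parental alleles
  segregate, with within-family allele frequency ≈ 0.5;
* founder-specific allelic series at QTL, specified as a founder × QTL
  effect matrix relative to the common parent;
* plot-level phenotypes over several environments with noise calibrated
  to a target line-mean heritability (0.6–0.9 is the realistic range
  for these traits; 0.85 is the default used in tests);
* repeated 1–10 ratings per season following a logistic lesion-progress
  curve scaled by the plot's phenotypic value, with bounded noise,
  clipped and rounded to the integer scale (the generative form of the
  curve is a simulator choice; only the score scale is prescribed by
  the source data);
* raw-call corruption for the HMM stage: heterozygote dropout (default
  0.8), call-level allele errors, and missingness (default 0.5),
  matching the reported error profile of the original genotype data.

One deliberate design choice deserves emphasis: the RIL mosaic is drawn
directly at the line level as a two-state Markov chain whose switch
probability between adjacent markers is the Haldane fraction $r(d)$ of
their map distance, with residual heterozygosity overlaid as a second
chain with stationary frequency $2^{-s}$. A generation-by-generation
selfing simulation would instead realise the RIL map-expansion
$2r/(1+2r)$ between markers. The direct parameterisation is used
because the linkage maps this package consumes are themselves estimated
from RIL populations — their distances already express RIL-level
recombination — and because it makes the simulator's behaviour exactly
testable against $r(d)$. The selfing depth of the original RIL panel is
not stated in the source; it is exposed as a parameter with default 6.

What the generator does **not** emulate: real maize linkage
disequilibrium structure, gene content, segregation distortion, or the
cross-incompatibility exclusions of particular families. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to every artefact of real data.

Every stochastic operation takes an explicit seed and runs under a
temporary RNG state (`with_seed()`), so no call perturbs or depends on
global RNG state; the pipeline fans one master seed out to per-stage
seeds by stable string hashing (`derive_seed()`), which lets any stage
be re-executed in isolation with identical output.

## Numerical choices

* All F tests are computed from sums of squares accumulated per family
  block; $-\log_{10} p$ is evaluated through `pf(log.p = TRUE)` so
  strong signals never underflow, and perfect fits are capped at 350.
* A marker counts as segregating in a family when its residualised sum
  of squares exceeds `1e-8 × n`; monomorphic-in-family columns
  contribute nothing and reduce the nested term's numerator df.
* Negative variance-component solutions are truncated at zero and
  flagged.
* Viterbi backtracking ties go to the previous state; forward-selection
  ties go to smaller p, then chromosome order, then cM.
* Dosage writers format to 4 decimals; readers reject unsorted maps,
  duplicated markers and out-of-range dosages with the offending line
  or chromosome named.

## Problem sizes used in the tests

The statistical acceptance checks run at the scale the properties are
stated for: 10 families × 150 RILs with ~500 markers for threshold
calibration (200 permutations, 200 null scans) and eight-QTL recovery;
2000 lines × 20,000 projected variants with 100 subsamples for RMIP
behaviour; 1000–2000 lines for variance-component and heritability
recovery; 24 × 140 lines for the partial-correlation study; ~5500
marker pairs for the epistasis null. These sizes were chosen as the
smallest at which the binomial/Monte-Carlo tolerances quoted in the
tests are meaningful.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(n_families = 6, n_rils = 80, n_chrom = 3,
                  n_dense = 1500, n_qtl = 4, n_perm = 100,
                  n_subsamples = 40, seed = 7)
res <- run_pipeline(cfg, dir = "namhr_demo")
res$model
head(res$associations)
cat(make_report("namhr_demo")$text, sep = "\n")
```

## Known limitations

* LS means and variance components are fixed-effects/method-of-moments
  approximations to REML; they are exact on balanced designs and
  adequate near balance, but not for severely unbalanced data.
* Composite interval mapping is not reimplemented; the single-family
  scan is a simple marker regression.
* The GWAS dense-variant model fits one across-population slope; rare
  founder-specific dense alleles are better served by the joint-linkage
  stage.
* Candidate-gene annotation (nearest-gene lookup) is out of scope; all
  outputs carry coordinates only.
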