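---
title: "Methods: strand-aware A-to-I editing detection and differential editing analysis"
author: "edscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware A-to-I editing detection and differential editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscan)
```

## Scope and model

A-to-I RNA editing deaminates adenosine to inosine, which sequencers read as
guanosine: on the coding strand an edited site appears as an A>G variant, on
the non-coding strand as T>C. `edscan` starts from per-sample, per-site
base-quality-filtered pileup counts (base quality >= 25 is an upstream
contract of the count table) and carries a case/control cohort through five
stages: editing-site detection with an artifact filter cascade, differential
editing by binomial GLM likelihood-ratio tests, cross-dataset consensus,
weighted co-editing network analysis with hub extraction, and clinical
association / ROC analysis. A synthetic-data generator with planted ground
truth exercises all of it without any external download.

The editing level at a site is the fraction of edited over informative
reads,

$$\ell = \frac{n_G}{n_A + n_G}$$

on the plus strand (and $n_C/(n_T+n_C)$ on the minus strand); reads on the
two other bases never enter the denominator, and the level is missing (not
zero) when the denominator is empty or total depth is below the
callability floor.

## Site detection and the filter cascade

A site is called in a sample when sequencing depth >= 10, alternative
allele depth >= 2 and alternative allele frequency (AAF, alt over ref+alt
reads) >= 1%; all three bounds are inclusive. A site enters the candidate
set when called in at least one sample.

Strand consistency comes from the gene models, since editing is defined on
the transcript: A>G candidates are kept only inside plus-strand genes and
T>C candidates only inside minus-strand genes. Candidates outside genes,
with other substitution types, on the wrong strand, or overlapping genes on
both strands are dropped with explicit reasons (`intergenic`, `non_AG`,
`strand_mismatch`, `ambiguous_strand` — the last is a conservative choice
where strand cannot be decided).

Remaining candidates pass a four-rule cascade; a candidate on the
known-editing-site whitelist (a REDIportal-style catalogue) bypasses all
four rules. A non-whitelisted candidate is removed when any rule fires, and
the first firing rule is logged:

1. **Sequence context** — inside a maximal single-nucleotide run of five or
   more bases (computed from the reference sequence, not an annotation),
   inside an annotated simple-repeat interval, or on the mitochondrial
   contig.
2. **Alignment artifacts** — within six nucleotides (genomic distance,
   strand-agnostic) of a splice-junction-adjacent base; flagged within one
   nucleotide of an indel; or with a cross-sample median relative
   alt-read position <= 0.04 or >= 0.96. The read-position rule is a
   site-level summary of a per-read filter: each cell of the count table
   carries the median relative position of its alt-supporting reads, and
   the cascade takes the median of those medians across samples. This
   reproduces the intent (reads supporting a variant only near read ends
   indicate misalignment) without storing per-read data.
3. **Known germline variation** — present in the SNP blacklist (a
   dbSNP-style catalogue).
4. **Germline allele-fraction pattern** — AAF equal to 100% or between 40%
   and 60% in more than 90% of the *callable* samples (depth >= 10). Using
   callable samples as the denominator is deliberate: AAF is undefined at
   depth zero, and counting uncovered samples against the 90% would let
   true heterozygous SNPs through in sparse data.

Finally, the high-confidence rule retains an event when its level is >= 1%
in at least two samples, or when the site is whitelisted. Every candidate
appears exactly once in the filter log (one of the drop reasons above,
`low_confidence`, or `retained`), which makes the cascade auditable against
a truth table.

Functional consequences are annotated from the gene models: CDS events are
translated on the coding strand with the standard codon table (missense /
synonymous / stop gained), exonic non-CDS events are 5'/3' UTR by
strand-aware position, non-exonic intra-gene events are intronic, and genes
without a CDS yield `non_coding`.

## Differential editing

Per event, the (edited, unedited) read counts of each usable sample
(depth >= 10) are modelled with a binomial GLM, logit link, group as the
only covariate, and compared to the intercept-only model with a
likelihood-ratio test on one degree of freedom. Counts rather than levels
are modelled because depth carries real information: a level of 0.10 at
depth 200 is far stronger evidence than at depth 12. With one binary
covariate this GLM is saturated in the two group means, so the
maximum-likelihood fit is analytic — per-group proportions under the
alternative, the pooled proportion under the null — and the deviance
difference equals twice the log-likelihood difference. The analytic form
also handles separation exactly: a group with zero edited reads contributes
its boundary likelihood directly and the statistic stays finite. Unit tests
verify agreement with `stats::glm` deviances to 1e-8 and with a
numerical likelihood-maximization oracle to 1e-6.

Significance is the raw p < 0.05, with a Benjamini-Hochberg column
reported alongside for users who want FDR control; events with fewer than
two usable samples in either group are marked untestable rather than given
p = 1. A Gaussian-on-levels mode (`family = "gaussian"`) is available for
sensitivity analysis.

**Calibration and overdispersion.** The binomial model assumes all
between-sample variation at a site is sampling noise. When true per-sample
levels vary biologically (the generator's beta hierarchy with finite
concentration $\kappa$), the binomial GLM is anticonservative — at depth 50
and $\kappa = 30$ the variance inflation is roughly
$1 + (\bar d - 1)/(\kappa + 1) \approx 2.6$, and the nominal 5% test
rejects null events far more often. The calibration study therefore
simulates null events under the model's own assumptions
($\kappa = \infty$: every sample sits exactly at the group mean), where the
type-I error is within [0.03, 0.07] at the 5% level over 1,200 events.
This is a property of GLM-based differential-editing testing in general,
not of this implementation, and is the reason the consensus stage
(requiring the same event in at least three datasets) matters in practice.

Cross-dataset consensus joins per-dataset results on the `contig:pos` key
(gene-level consensus on `gene_id`), with an optional requirement that the
sign of the level difference agree. Differentially edited genes are genes
containing at least one significant event. The companion expression screen
is a per-gene Welch t-test on log2(x+1) with BH FDR and a hit flag at
FDR <= 0.05 and |logFC| >= 1 (both inclusive); genes with zero variance in
both groups get p = 1 by convention. PCA of the editing matrix mean-imputes
missing cells per event and uses column-centred SVD (`prcomp`).

## Co-editing network

The network is unsigned: adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$
on pairwise-complete Pearson correlations (events with more than 50%
missing cells or constant profiles are excluded and logged). The power
$\beta$ is chosen by scale-free topology fit: for each candidate power the
connectivity distribution is binned, $\log_{10} p(k)$ is regressed on
$\log_{10} k$, and the fit index is the $R^2$ sign-adjusted by the slope;
the smallest power reaching 0.8 wins, otherwise the argmax is returned with
a warning. Worth knowing: two equal-sized co-editing blocks are *not*
scale-free (no power reaches the target — the warning path is expected
there), while heterogeneous, hub-like correlation structure reaches the
target at moderate powers; both behaviours are covered by tests.

Topological overlap uses the standard form

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \neq i} a_{iu},$$

with the shared-neighbour sum excluding $u \in \{i, j\}$, which keeps
$\mathrm{TOM}_{ij} \le 1$; tests compare against an explicit triple-loop
oracle at 1e-10.

Modules come from average-linkage clustering of $1 - \mathrm{TOM}$ with a
static cut at a fraction of the maximum merge height. The default fraction
is 0.95: between unrelated events TOM dissimilarities concentrate just
below 1, so genuine co-editing blocks attach far down the dendrogram and
the final merges (at 0.994-0.9998 of the maximum in simulated two-block
data) only join blocks to background — cutting just below them separates
blocks without fragmenting them. A static cut was chosen over dynamic tree
cutting for determinism and transparency; the height is exposed. Clusters
smaller than `min_size` (default 10) are grey (unassigned); surviving
modules are named by decreasing size with the conventional WGCNA colour
sequence, so the largest module is always turquoise and naming is
reproducible. The module eigengene is the first principal component of the
per-event-standardized module submatrix, unit norm, sign-oriented to
correlate non-negatively with the module's mean profile. Module-trait
relationships are Pearson correlations (two-sided t test) of eigengenes
against group (control = 0, case = 1) and the hormone features, and the key
module is the one most significantly associated with group.

**Hub extraction.** Hubs are the top ten module members by degree after
binarizing intramodular edge weights at a 0.4 cutoff, with ties broken by
smaller differential-editing p-value, then event id. The edges are defined
on the *unpowered* correlation strength $|r|$, not on $a_{ij} = |r|^\beta$:
after raising to a typical selected power (6-17 in the simulations) even
$|r| = 0.9$ pairs fall below any fixed cutoff and the graph empties, so a
0.4 threshold is only meaningful on the correlation scale. The
`edge_on = "adjacency"` option restores thresholding of the powered
adjacency for users who want it.

## Clinical association and ROC

Hub-hormone and editing-expression (cis) associations are complete-case
Pearson correlations with two-sided t-based p-values on n-2 degrees of
freedom; pairs with fewer than three complete observations or a constant
vector are untestable. No multiplicity correction is applied over the
hub-by-hormone grid (BH is available downstream via `p.adjust`).

ROC analysis treats higher marker values as case-like. The curve is
evaluated at every distinct threshold and the AUC is the Mann-Whitney U
statistic with half credit for ties, which the tests verify equals the
trapezoidal integral of the curve exactly. Multi-marker panels are combined
by unpenalized logistic regression of the label on the marker levels; the
score is the fitted linear predictor, making the AUC invariant to affine
rescaling of any marker. Exact duplicate markers are dropped before the
fit; if the fit separates, a ridge-stabilized Newton fit with a small fixed
penalty (1e-6 per observation, intercept unpenalized) is used and flagged.
Reported AUCs are in-sample, matching common practice for discovery
cohorts; at n = 22 this is optimistic (simulated all-noise three-marker
panels average an in-sample AUC around 0.7), so the in-sample label should
be taken seriously when comparing panels.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the scale of a small discovery cohort:

* **Cohort**: 12 case and 10 control samples by default.
* **Genome**: one main contig with 20 alternating-strand three-exon genes
  (internal CDS, hence real UTRs, introns and four junction-adjacent bases
  per gene), a mitochondrial contig with one gene, planted homopolymer runs
  (>= 6 nt), simple-repeat tracts and Alu-like intervals inside exons.
* **Depth**: negative binomial, mean 50, dispersion 5 — chosen so a
  realistic fraction of cells falls below the depth-10 floor and
  missingness is exercised everywhere.
* **Editing**: 200 sites with baseline levels uniform on [0.05, 0.35];
  100 differential with a level shift of 0.15; per-sample levels are beta
  distributed around the group mean with concentration $\kappa = 30$
  (set $\kappa = \infty$ for exact-binomial data). Edited reads are
  binomial(depth, level), appearing as G at plus-strand A sites and C at
  minus-strand T sites. 30% of clean editing sites are whitelisted.
* **Hub block**: 20 of the differential sites share a latent factor with
  loading 0.9 (per-site level s.d. 0.12) and a group shift of 2 latent
  units, so the block is both internally correlated and group-driven; hub
  sites are whitelisted (known sites, as hub events typically are).
* **Germline SNPs**: 100 heterozygous (allele fraction 0.5 in every
  sample) and 50 homozygous (1.0); 95% are blacklisted, matching the high
  catalogue coverage of common SNPs — the AAF-pattern rule has to catch
  the remainder.
* **Decoys**: 200 edit-like sites placed specifically inside homopolymers,
  simple repeats, the mitochondrial gene, junction windows, near-indel
  flags and read-end artifacts (median alt read position <= 0.04), one
  class per site so each removal reason can be checked against truth.
* **Errors**: each read miscalls with probability 0.001, uniformly to the
  other three bases.
* **Hormones**: value = baseline + loading x latent factor + group effect
  + Gaussian noise, with baselines and spreads typical of a PCOS discovery
  cohort (e.g. LH 7.3 IU/L in controls with a +13 IU/L case effect, FSH
  unchanged) and LH additionally loaded on the hub factor (+2.5 IU/L per
  latent s.d.), so hub-hormone association has a planted positive control.
  The LH/FSH ratio is computed, not drawn.
* **Expression**: log-normal per-gene baselines; genes hosting a hub site
  get a log2 cis term of 3 x editing level, for the cis-correlation tests.

What it does **not** emulate: read-level alignment artifacts beyond the
read-position summary, base-quality structure, strand bias, covariates such
as age or BMI, linkage between SNPs, real Alu sequence context, or
expression-editing coupling beyond the simple cis term. Passing tests on
this generator therefore demonstrates that the *algorithms* implement their
contracts and recover planted structure under the assumed noise model — not
that the filter thresholds are optimal for any particular real library
preparation.

## Problem sizes and numerical choices

The test and validation suites run at deliberately desk-scale sizes: the
default 850-site simulation for cascade validation; 1,200 binomial null
events for calibration; 200 events per effect size for power ordering; 50
random instances against the likelihood oracle; 20-node networks against
the TOM/degree oracles; a 100-event network (20 hub + 80 background) for
module recovery; 50 replicate cohorts for hormone association. Determinism
is end-to-end: every stage is a pure function of (inputs, config, seed),
verified by byte-identical md5 manifests of two complete pipeline runs.

Other numerical conventions: levels and AAFs are exact ratios of integer
counts; the homopolymer rule scans the reference rather than trusting an
annotation; hub ties break by differential p then event id; module labels
are invariant to input order up to the size-ordered colour naming; BED
files are converted between 0-based half-open (on disk) and 1-based closed
(internal) coordinates at the I/O boundary, property-tested as a bijection.

## Known limitations

* The binomial GLM ignores biological overdispersion (see above); a
  beta-binomial test would be the natural extension.
* Strand assignment requires gene models; intergenic editing (and editing
  in bidirectionally transcribed regions) is out of reach by design.
* The read-end filter uses a site-level summary; pathological mixtures
  (half the reads at each end) can evade it.
* In-sample AUC at small n is optimistic; cross-validation is left to the
  user's discretion.
* The simplified consequence annotator handles single-nucleotide
  substitutions in single-transcript gene models only — no splice-site,
  multi-transcript or regulatory annotation.
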