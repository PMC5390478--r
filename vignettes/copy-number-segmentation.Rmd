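---
title: "Methods: double sliding-window copy-number and cnLOH segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double sliding-window copy-number and cnLOH segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dswseg)
```

## The problem and the signals

Somatic copy-number alterations (SCNAs) and loss of heterozygosity (LOH)
reshape cancer genomes.  Paired tumor/normal whole-genome sequencing exposes
them through two complementary signals:

* the **read-depth log ratio** per genomic bin,
  $logr_i = \log_2(tRD_i / nRD_i)$, where $tRD_i$ and $nRD_i$ are the
  numbers of reads overlapping bin $i$ (2 kbp by default) in tumor and
  normal; $logr = 0$ is copy-neutral, a hemizygous deletion sits near $-1$,
  a single-copy gain near $+0.58$;
* the **B-allele fraction** $BAF_i = alt_i / (alt_i + ref_i)$ at
  heterozygous SNPs (called in the normal sample at known sites), expected
  0.5 in diploid tissue and displaced by any allelic imbalance.

Copy-neutral LOH (cnLOH) — the lost allele replaced by a duplicate of the
survivor — is invisible in read depth and shows up only in BAF, which is why
both signals are segmented together.  With no BAF input the package still
segments read depth alone, but then cnLOH cannot be detected.

## Preprocessing

**Library-size correction.**  Differences in the total aligned reads bias
$logr$ by an additive constant.  We estimate the mode of the finite
log-ratios of each chromosome and subtract the *median of the
per-chromosome modes*: a single aberrant chromosome (say an arm-level gain)
moves one mode but not the median.  The mode estimator is a histogram with
bins of width 0.05 log2 units *centred on multiples of 0.05* (ties resolved
toward the bin nearest 0).  Centring the bins on 0 makes the correction
exactly zero on an unbiased noise-free genome; the phase of the histogram is
otherwise arbitrary.

**Mirroring and smoothing BAF.**  Raw BAF is symmetric about 0.5, so
smoothing it directly would cancel the divergence we want to measure, while
mirroring first ($|0.5 - BAF|$) then smoothing overestimates the divergence
of genuinely balanced SNPs.  The two are blended per SNP:

$$cBAF_i = H \cdot |0.5 - M_9(BAF_i)| + (1 - H) \cdot M_9(|0.5 - BAF_i|),
\qquad H = 1 - 2\,|0.5 - BAF_i|,$$

where $M_9$ is a running median over the 9 SNPs centred on $i$.  $H$
measures how heterozygous-looking the raw observation is: near 0.5 the
smooth-then-mirror branch dominates (avoiding the overestimate), near 0 or
1 the mirror-then-smooth branch does.  We take the $x$ in $H$ to be the raw
$BAF_i$ at the SNP itself; $cBAF$ always lies in $[0, 0.5]$, with values
near 0.5 meaning near-complete allelic imbalance.  At the first and last
four SNPs of a chromosome the median window shrinks symmetrically to the
available SNPs — no padding, and smoothing never crosses a chromosome
boundary.  (`stats::runmed`'s end rule is *not* this symmetric shrinking
window, which is why the filter is implemented in the package.)

**Missing data.**  Bins where either sample has zero depth carry a missing
marker and are excluded from all window and segment means; no pseudocounts
are added, because they would distort exactly the deep-deletion bins that
matter.

## Segmentation

Two adjacent, non-overlapping windows of $w$ bins slide along each
chromosome.  At the boundary where they touch, the compound score

$$S = \left(\frac{\Delta \overline{logr}}{\tau_{logr}}\right)^2 +
      \left(\frac{\Delta \overline{cBAF}}{\tau_{BAF}}\right)^2$$

is computed from the absolute differences of the window means; $S > 1$
signals a change.  Normalizing by $\tau^2$ (rather than $\tau$) makes
$S > 1$ coincide exactly with "the mean difference exceeds its threshold"
in the single-signal case and keeps the threshold-decay argument below
dimensionally consistent.  A true step raises $S$ at several nearby
boundaries, so only boundaries that are local maxima of $S$ within $\pm w$
are reported; exact ties keep the leftmost.

The log-ratio term averages non-missing bins, and a boundary is skipped
when more than half of either window is missing (means near centromeres and
assembly gaps are too unstable to trust).  The cBAF term averages the
individual SNPs inside each window — not the bin-resampled track — so a
SNP-sparse bin costs nothing; the term is dropped only when a window holds
no SNP at all.  When a signal is constructed directly on the bin grid
without a SNP table, each non-missing bin counts as one observation.

**Multiple scales.**  A single window size trades off sensitivity against
localization, so detection is repeated: each pass multiplies the window by
1.5 (`ceiling`, so growth is strict) and both thresholds by $1/\sqrt{1.5}$
— the factor by which the standard error of a window mean shrinks when the
sample grows 1.5-fold.  Passes run while both thresholds remain strictly
above their merge thresholds.  All pass-1 breakpoints are accepted; a
later-pass breakpoint joins the consensus only if it is farther than the
current window size (in bp — the spec leaves bins-vs-bp open, and bp keeps
the rule scale-aware) from every accepted breakpoint on its chromosome.

**Segments and merging.**  Consecutive consensus breakpoints (with
chromosome ends as implicit boundaries) delimit segments; each carries its
mean $logr$ over non-missing bins and mean $cBAF$ over contained SNPs.
Adjacent segments merge when *both* $|\Delta\overline{logr}| <
\tau_{merge_{logr}}$ and $|\Delta\overline{cBAF}| < \tau_{merge_{BAF}}$
(the BAF condition holds vacuously when either side has no SNP support, and
is ignored in log-ratio-only mode).  Sweeps run left to right until a fixed
point; merged means are support-weighted.

Defaults: initial window 10 bins, $\tau_{logr} = 0.4$, $\tau_{BAF} = 0.15$,
$\tau_{merge_{logr}} = 0.1$, $\tau_{merge_{BAF}} = 0.05$.  The initial
thresholds are deliberately permissive at the coarsest scale; the merge
thresholds set both the loop's stopping point and the final resolution of
the piecewise fit.

## cnLOH calling and recurrence

A segment is cnLOH when it is copy-neutral yet allelically collapsed:

$$|\overline{logr}| < \tau_{cnLOH_{logr}} \quad\text{and}\quad
  0.5 - \overline{cBAF} < \tau_{cnLOH_{BAF}},$$

both strict, defaults 0.1 and 0.1.  Two guard filters — minimum segment
length 1 Mbp and minimum 20 supporting SNPs, each disabled by 0 — suppress
spurious short calls; segments with no SNPs are never flagged.  Recurrence
across a cohort partitions the genome at all call endpoints and counts, for
every atomic interval, the samples covering it (overlapping calls within
one sample are merged first, so a sample contributes at most 1 per base).
The counting runs on genomic-ranges coverage machinery and is tested
against a per-base brute-force oracle.

## The simulator

The simulator emulates the full data-generating process so the whole
pipeline can be tested without protected patient data:

1. **Depth model.**  A first-order chain is learned from a normal track by
   counting ordered pairs of consecutive bin depths (never across a
   chromosome boundary).  A fresh sequence is drawn by inverse-transform
   sampling from the conditional distributions (marginal fallback for
   unseen states), then denoised with a width-9 median filter into the
   *baseline* — preserving the spatial correlation of real coverage while
   removing its sampling noise.
2. **Samples.**  The simulated normal is an independent Poisson draw around
   the baseline.  Somatic events (deletions, amplifications, cnLOH;
   uniform over types, log-uniform sizes 1–30 Mbp, 20 per genome by
   default) act on two haplotype copy-number tracks $cn_A, cn_B$
   (1/1 outside events), and the tumor is Poisson around
   $baseline \cdot (2c + (1-c)(cn_A + cn_B))/2$ for normal-cell
   contamination $c$ — a fraction $c$ of cells diploid, the rest carrying
   the event, depth normalized to the diploid baseline.
3. **BAF.**  Heterozygous SNPs follow a Poisson point process with mean
   spacing 1.5 kbp.  Each SNP's B allele lands on haplotype A or B with
   probability 1/2 (without this, mirroring would have nothing to mirror);
   the alt count is $\mathrm{Binomial}(n, p)$ with $n$ the simulated
   normal depth at the SNP's bin and
   $p = (c + (1-c)\,cn_{Bhap}) / (2c + (1-c)(cn_A + cn_B))$ — the fraction
   of DNA copies carrying the B allele in the mixture.  In a pure tumor
   cnLOH region this degenerates to BAF exactly 0 or 1.

Events are snapped to bin boundaries so the ground truth lives on the same
grid the analysis uses.  When no real normal track is supplied, a synthetic
one (Poisson noise around a slowly drifting wave at mean depth 100) trains
the pair model.  All randomness flows from one seed; identical parameters
and seed give identical outputs.

What the simulator does **not** emulate: GC-content and mappability bias,
read-level artifacts, subclonal mixtures beyond the single contamination
fraction, and SNP ascertainment noise.  Tests passing on simulated data
therefore demonstrate the segmentation mechanics — not robustness to the
systematic biases of real libraries, which this method (by design) does not
correct for.

## Evaluation statistics

Breakpoint accuracy is scored by greedy one-to-one nearest matching within
a tolerance (default: one initial window in bp; the distance ranking is
tie-broken by position, so matching is deterministic): matched pairs are
true positives, unmatched calls false positives, unmatched truth false
negatives; precision, recall and F-measure follow, with $P = 0$ for empty
call sets and $F = 0$ when $P + R = 0$.  Call sets are also comparable by
**blockization**: the genome is cut into 100-bp blocks, a block is
SCNA-labelled when its midpoint lies in a called non-neutral segment
($|\overline{logr}|$ above 0.1 by default binarizes the real-valued
output), exclusion regions drop blocks by the same midpoint rule, and two
annotations are compared by the Jaccard index (intersection over union of
labelled blocks, 0 for an empty union).

## Numerical choices and degenerate inputs

* Medians of an even number of values are the mean of the two central ones.
* Exact score ties keep the leftmost boundary; merge sweeps are
  left-to-right to a fixed point — all deterministic.
* A window growth of exactly 1.5 with `ceiling` guarantees strict growth
  even for tiny windows.
* Chromosomes shorter than $2w$ bins are skipped at that scale; an
  all-missing track is an error for the corrector; empty call sets are
  legal everywhere in evaluation.
* Depth-chain states never seen as a pair predecessor fall back to the
  marginal distribution.

## Resolution limits worth knowing

* Breakpoints live on bin boundaries; nothing is localized below the bin
  width.
* A cnLOH boundary is carried only by SNPs.  When the bin adjacent to a
  true boundary happens to contain no SNP (probability
  $e^{-2000/1500} \approx 0.26$ per bin at default densities), the data
  genuinely cannot distinguish neighbouring cut positions, and the detected
  boundary can sit one bin off.  Noise-free simulations therefore recover
  depth-driven (deletion/amplification) boundaries *exactly*, and
  BAF-driven ones to within one bin.
* Exact recovery also requires every copy-number piece to span at least
  two initial windows; the generator's `min_event_gap` parameter exists to
  construct such configurations, and the default of 0 leaves placement
  unconstrained beyond non-overlap.
* Recall degrades with contamination: at $c$, a hemizygous deletion's
  expected log ratio shrinks to $\log_2(1 - (1-c)/2)$ and BAF contrast
  shrinks similarly, so small events fall below the detection thresholds
  first.

## Problem sizes used in the test-suite

The packaged tests run the full pipeline on simulated genomes of 6–60 Mbp
at the default 2-kbp bin (3,000–30,000 bins, roughly 4,000–40,000 SNPs),
with larger Monte-Carlo checks (e.g. $10^5$ Poisson bins, $10^4$
random-input formula oracles) where moments are asserted within three
standard errors.  These sizes exercise every code path at full fidelity;
the method itself is linear per pass in the number of bins and runs
whole-genome inputs the same way.

## A worked example

```{r, eval = FALSE}
p <- simulation_params(genome = c(chr1 = 10e6, chr2 = 10e6),
                       n_events = 4, event_size_range = c(1e6, 2.5e6),
                       contamination = 0.2)
sim <- simulate_tumor_normal(p, seed = 42)
sig <- joint_signal(sim$tumor, sim$normal, sim$baf)
fit <- dsw_segment(sig, cnloh = cnloh_params())
fit
coef(fit)
plot(fit)
ev <- match_breakpoints(fit$breakpoints, truth_breakpoints(sim),
                        tolerance_bp = 20000)
ev
```
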