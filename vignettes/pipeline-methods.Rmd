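---
title: "Methods: pooled MaMTH-HTS screen analysis and functional validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled MaMTH-HTS screen analysis and functional validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamthscreen)
```

# Scope and model

`mamthscreen` analyses pooled mammalian membrane two-hybrid (MaMTH-HTS)
protein-protein interaction screens and the downstream assays used to
validate their hits. In a pooled screen, a membrane "bait" protein
(here, wild-type or F508del CFTR) is tested against an ORFeome "prey"
library in a mixed cell population; cells carrying interacting pairs are
enriched by sequential FACS sorting, prey cassettes are PCR-amplified in
two technical replicates and deep-sequenced, and interaction signal is
taken proportional to each prey's read counts per million (CPM). The
package covers six stages:

1. **Read quantification** (`index_reference`, `assign_reads`,
   `counts_to_cpm`): exact k-mer assignment of reads to ORFs.
2. **Candidate calling** (`call_candidates`, `replicate_overlap`): the
   hard count filter that defines candidate interactors.
3. **Frequent-flier filtering** (`rank_product_test` and friends): a
   rank-product consensus across control-bait screens with a
   permutation null.
4. **Interactome comparison** (`compare_baits`, `export_edges`): set
   bookkeeping between baits and network edge export.
5. **Traffic screen analysis** (`traffic_screen`): QC, 5x5
   well-neighbourhood Z-scores and enhancer/inhibitor gene calls for a
   high-content siRNA screen of a fluorescent CFTR traffic reporter.
6. **Functional assay statistics** (`flipr_*`, `fis_auc`,
   `ussing_metrics`, `wb_fold_change`, `normalize_and_test`).

A synthetic-data module generates every input the pipeline consumes, so
each stage can be tested end to end without raw sequencing or imaging
data.

# Read quantification

Reads are assigned to ORFs by exact matching of k-mers (default
`k = 31`, a standard pseudo-alignment scale at which random ORF-length
sequences essentially never collide). A k-mer occurring in two or more
ORFs is marked ambiguous; a read is counted for an ORF only if *all* of
its unambiguously mapping k-mers agree on that ORF and at least one
k-mer is unambiguous. Reads failing this (shared-region reads,
conflicts, unmatched or too-short reads) are discarded and tallied, so
`assigned + discarded = total` always holds. Matching is forward-strand
only because the prey cassette is amplified with fixed-orientation
cassette-specific primers. There is no mismatch tolerance: exact
matching keeps the stage deterministic and checkable against a naive
substring-search oracle, at the cost of dropping reads with sequencing
errors (the generator emits error-free reads, so tests are exact).

CPM is the usual `count * 1e6 / library_size`; zero-library columns
become zeros with a warning rather than an error, since an empty
replicate is a recognisable upstream failure, not a user mistake.

# Candidate calling

The candidate filter removes an ORF when its total count is below 3 in
*both* technical replicates — i.e. an ORF is retained when at least one
replicate has 3 or more reads. This literal reading makes the
"detected in both replicates" subset a strict subset of the candidate
list, which is exactly how the replicate-overlap robustness figure
behaves (e.g. 209 of 224 candidates, 93%). Per-replicate "detected"
uses the same threshold; percentages are reported at integer precision
with round-half-to-even. Single-replicate tables error unless the
caller opts in explicitly.

The pipeline applies frequent-flier removal *before* per-bait totals
are compared, so downstream counts refer to flier-free lists.

# Frequent fliers: rank products with a permutation null

Preys that light up across screens of many unrelated control baits are
assay artifacts ("frequent fliers"). With 9 control screens, each
screen's CPM column is ranked descending (highest CPM = rank 1; ties
get average ranks, which conserves rank sums; zero-CPM preys are simply
tied last). A prey's rank product is the geometric mean of its
per-screen ranks; small values mean consistently strong signal.

The null distribution is obtained by independently permuting each
screen's rank column (default 100,000 iterations) and recomputing rank
products. The per-prey p-value is the fraction of iterations in which
the randomized rank product *at that prey's position* is less than or
equal to the observed one. Two counting choices deserve comment:

* **`<=` versus `<`**: with `<=` (the default), completely tied data
  give p = 1 for every prey, which is the only sensible degenerate
  behaviour; both comparisons are exposed.
* **Zero p-values**: the default divides the count by the number of
  iterations without a +1/+1 correction, so a prey never beaten by the
  null gets p = 0, read as "below 1/n_iter". A consequence is that a
  threshold of exactly 0 must not flag anything; `flag_frequent_fliers`
  treats `alpha = 0` as "flagging disabled". The `correct = TRUE`
  toggle gives the conservative `(count + 1) / (n_iter + 1)` form.

P-values are adjusted by Benjamini-Hochberg and preys with adjusted
p <= 0.05 (the package default; the threshold is exposed because
published flier counts do not pin it down) are flagged and removed from
candidate lists. Tests verify the Monte-Carlo p against exhaustive
enumeration of all joint permutations on small instances, uniformity of
the null p-values (KS distance below the 1% critical value at 1,000
preys and 10,000 iterations), and spike-in recovery (5 fliers at
100-fold enrichment among 1,000 preys are always flagged at
alpha = 0.05 across 20 seeds, with permutation depth 2,000 per seed —
enough because a true flier's rank product is never approached by
permuted data, so its p-value is 0 at any depth).

# Interactome comparison

Set algebra between two flier-filtered candidate lists: shared preys,
per-bait uniques and the union, with the invariants
`|shared| + |unique_a| = |set_a|` and
`union = |a| + |b| - |shared|` property-tested on random sets. The
shared-of-union percentage is reported at one decimal; on the published
counts (224 and 269 candidates, 46 shared) this gives 10.3%, and the
package reports that computed value rather than attempting to match any
other rounding. Edge lists are exported as plain TSV
(`bait / prey / category` with `shared`, `bait_a_only`, `bait_b_only`),
deterministically ordered so re-export is byte-identical; PSI-MITAB
metadata does not exist for this kind of dataset, so no attempt is made
to fake it. External annotations may be joined from a pre-built table
but are never fetched.

# High-content traffic screen

Inputs are per-image well summaries (median surface-reporter intensity
per image, plus cell count, focus and total-expression metrics);
image segmentation itself is upstream. The analysis chain is:

1. **QC**: an image is excluded if it has fewer than 100 cells, is out
   of focus, or shows negligible reporter expression. The expression
   floor defaults to the 10th percentile of the plate's
   negative-control (siNeg1) images, falling back to all images when a
   plate carries no controls; an absolute threshold can be supplied.
2. **Well summary**: median of the well's valid image medians. Wells
   with no valid images are invalid and excluded downstream.
3. **Neighbourhood Z-score**: each well is referenced to the median of
   the valid wells in the 5x5 window centred on it (truncated at plate
   edges, centre included — excluding it is a toggle). The scale is the
   plate-level robust SD of these local residuals
   (`1.4826 * MAD`): a 25-well local MAD is noisy and collapses to zero
   under ties, so the plate-level residual scale is the
   B-score-adjacent compromise; per-neighbourhood MAD and
   negative-control SD are available as alternatives. `Z = 0` when the
   scale is zero. Z-scores are invariant to adding a constant to the
   plate and to positive rescaling.
4. **Aggregation and calls**: the reported Z of an siRNA is the median
   across its replicate wells and biological replicates (4 by design),
   with the number of valid replicates reported alongside. Hits are
   Z > +1 (increase) or Z < -1 (decrease). A gene is an
   enhancer/inhibitor when at least one of its siRNAs passes in one
   direction only, and *ambiguous* when siRNAs pass in both directions
   (the MIER2/SDHA1/ZNF22-type behaviour); consistently sub-threshold
   siRNAs (the FGL2 pattern, Z of 0.46 and 0.75) yield no call.

The plate generator uses a planar intensity gradient (linear in row and
column, amplitude as a fraction of background). A 5x5 median reference
removes a plane exactly in the plate interior, which is the property
the "gradient on, effects off" calibration exercises; well effects are
expressed in units of the image-level noise SD, so a +3 effect is a
+3 robust-SD spike. The generator does not model plate-edge
evaporation, cross-well contamination, or intensity-dependent variance;
passing calibration therefore demonstrates correctness of the
normalization chain, not robustness to every artifact real plates show.

# Functional assays

* **FLIPR membrane potential**: for wild-type CFTR the metric is the
  maximum post-forskolin `F/F0`, with `F0` the mean of all pre-event
  baseline scans (at least 4 by protocol; the single-last-scan variant
  is a toggle). For F508del, which needs forskolin plus potentiator
  before inhibitor addition, the metric is `F1 / F_inh`: last scan
  before the CFTR inhibitor over the post-inhibitor minimum. Both are
  invariant to rescaling the trace. Metrics are normalized to the
  CFTR-only control mean (per run) and compared by two-sided unpaired
  t-tests, pooled-variance by default with a Welch toggle; type-I error
  is verified near nominal by null simulation.
* **Organoid swelling (FIS)**: trapezoidal AUC of (relative area - 100)
  from stimulation to 60 minutes, series normalized to 100% at t = 0.
  Negative increments count; series extending past the endpoint are
  interpolated at it, shorter series integrate to their last point with
  a warning.
* **Ussing chamber**: `Ieq = Vte / Rte` pointwise (mV over Ohm cm^2,
  reported in uA/cm^2). CFTR activity is the difference of plateau
  medians: post-forskolin window median minus the post-amiloride,
  pre-forskolin baseline median; the inhibitor delta is analogous.
  Median plateaus were chosen over means for robustness to single-scan
  spikes; window edges are the event times.
* **Western blots**: band B and band C intensities are first normalized
  to the calnexin loading control, then fold changes are taken against
  the mean normalized baseline (siNeg1 + DMSO). A one-way ANOVA runs
  across conditions; as the post hoc comparison against baseline the
  package uses pairwise Welch t-tests with BH adjustment, clearly
  labelled in the output. A true Dunnett procedure needs multivariate-t
  quantiles and was deliberately left out; the substitute controls FDR
  rather than FWER and is reported as such.

# Synthetic data: what it does and does not emulate

Counts are negative binomial (`dispersion` is the NB size parameter):
overdispersion is what makes the rank-product null nontrivial, and NB
is the standard model for pooled-screen sequencing. Default conditions:
1,000-ORF libraries, background mean 0.5 reads per ORF, 50-fold
enrichment of true interactors, 100-fold enrichment of fliers in every
screen, dispersion 0.5, two technical replicates, nine control screens.
Reads are error-free forward-strand substrings of the ORF sequences;
sequencing error, PCR amplification bias and FACS gating physics are
out of scope, so quantification tests are exact rather than
statistical. Fewer than two control screens is rejected outright. Trace
and recording generators place drug events midway between scans and hit
their configured amplitudes exactly when noiseless, so metric tests
have closed-form expectations. All generators take an explicit seed and
are byte-reproducible.

Problem sizes used by the test-suite calibration runs (package
choices): 10,000 permutation iterations for the 1,000-prey null
uniformity check, 2,000 iterations per seed for 20-seed spike-in
recovery, 84 simulated plate sets (1,008 spiked wells) for traffic
spike recovery, and 10,000 repeats for t-test type-I calibration.

# Worked example

```{r example}
# simulate a bait screen plus the control stack, then run the pipeline
cfg <- screen_sim_config(n_orfs = 400, n_true_interactors = 10, n_fliers = 4,
                         seed = 7)
screen <- simulate_screen(cfg, "wtCFTR", emit_reads = FALSE)
controls <- simulate_control_screens(cfg)

cands <- call_candidates(screen$table, "wtCFTR", min_count = 3)
rp <- rank_product_test(controls$matrix, n_iter = 2000, seed = 8)
cands_clean <- remove_fliers(cands, flag_frequent_fliers(rp))

replicate_overlap(cands_clean)
table(screen$truth$role[screen$truth$orf_id %in% cands_clean$orf_ids])
```

# Known limitations

* Exact k-mer matching discards erroneous reads instead of rescuing
  them; on real FASTQ data counts will be slight undercounts relative
  to a mismatch-tolerant aligner.
* The permutation p-value resolution is 1/n_iter; at the default
  100,000 iterations the smallest nonzero p is 1e-5, and BH-adjusted
  significance for very large libraries may require more iterations.
* The traffic-screen scale estimator and the centre-well convention are
  field choices, not published ones; both are configuration-exposed and
  results near |Z| = 1 can move between conventions.
* The published flier count depends on an unreported adjusted-p cutoff,
  so only the procedure — not that count — is reproducible.
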