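---
title: "Methods: microdeletion calling from shallow-coverage cell-free DNA"
author: "niptcnv developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microdeletion calling from shallow-coverage cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-invasive prenatal testing (NIPT) sequences cell-free DNA from
maternal plasma at low coverage (5-20 million reads, ~0.1-0.4x). A
fraction `ff` of that DNA — typically 5-20% — is of fetal origin, so a
heterozygous fetal deletion lowers the read depth over the deleted
interval by only `ff/2` of the local level, a 2.5-10% dip buried in
Poisson counting noise and systematic coverage biases. `niptcnv`
detects such microdeletions (and duplications, and the maternal-origin
counterparts) from binned read counts, and quantifies how sensitivity
depends on fetal fraction, read count and aberration size.

## Model and pipeline

Reads are counted into fixed 20 kb bins by their leftmost mapped
position. For a sample with mean retained-bin count `mb`, the expected
depth shift of an aberration is

* fetal deletion/duplication: `-/+ mb * ff / 2`
* maternal (mother-only) deletion/duplication: `-/+ mb * (1 - ff) / 2`

The caller proceeds in four normalization steps plus segmentation:

1. **LOESS GC correction** (`gc_correct`): a curve of bin count against
   bin GC fraction is fitted on the sample's own mappable bins
   (`lowess`, span 0.3 — the span is not dictated by the method and is
   exposed in `norm_config`); each bin is multiplied by
   (global mean)/(fitted value at its GC). Bins with GC outside the
   fitted range use the nearest edge value. The correction is
   idempotent up to smoother tolerance.
2. **PCA residualization** (`fit_reference`, `pca_normalize`): a euploid
   reference cohort is GC-corrected, rescaled to a canonical read scale
   and stacked; the first `k = 15` principal components of the autosomal
   bin matrix capture shared "population" coverage artifacts. A query
   sample is rescaled, offset by the training mean, and its projection
   onto those components removed. Sex chromosomes are excluded from PCA
   (fetal sex and fetal fraction dominate them) and are rescaled
   independently; calls there are flagged lower-confidence.
3. **Bin filtering**: bins whose cross-cohort mean at the canonical
   scale is below `mu_min = 3.0` (about half the "ideal" ~6.5 reads per
   bin at the 1M-read-equivalent scale) or whose cross-cohort variance
   exceeds `v_max = 1.5` are dropped. On realistic synthetic cohorts
   this retains ~87-88% of mappable bins: the method's working regime.
   The variance is computed across cohort samples on GC-corrected,
   rescaled counts, before PCA removal (the alternative — after — is
   not distinguishable from the method description; trained-once-from-
   cohort semantics motivated the choice).
4. **Per-bin mean subtraction** (`center_profile`): stored per-bin means
   are rescaled to the sample's own depth and subtracted, so centered
   values sit around zero on the sample's count scale. Autosomes share
   one scale factor; each sex chromosome gets its own.

**Segmentation** (`cbs_segment`) is circular binary segmentation: for a
segment of `m` bins, the maximal two-sample statistic over all circular
arcs is computed; if significant at `alpha = 0.01` the arc's endpoints
become change-points and the pieces are recursed. Significance is
assessed by permutation with two speedups that do not alter the
decision semantics: (i) an exact pruning bound — every arc numerator is
bounded by the range of centered prefix sums while the denominator
grows with arc width, so scans stop when no remaining width can matter;
(ii) a Bonferroni shortcut — when the bound over all arcs is already
below `alpha/10`, the permutation is skipped. Permutations stop early
once non-significance is certain (exceedance count reaching
`floor(alpha * nperm) + 1`). The default is `nperm = 1000`; with early
stopping this gives ample p-resolution at `alpha = 0.01`.

**Classification** (`classify_segments`): with `d = |segment mean|`, a
segment is a maternal call if `d >= tau * mb * (1 - ff) / 2` and it
spans at least 200 kb; otherwise a fetal call if
`d >= tau * mb * ff / 2` and it spans at least 600 kb. `tau = 0.75`
trades sensitivity against specificity; ties at the threshold count as
significant. Deletion versus duplication follows the sign. When `ff` is
unknown a conservative 5% default is used and the output flagged —
below 5% fetal fraction calling is not recommended. Fetomaternal and
maternal events are reported under the single label "maternal". An
approximate z-score `mean / (sigma / sqrt(n_bins))` with a MAD-based
`sigma` from outside the segment annotates each call. Segments at 50%
or more of the fetal threshold that miss a call are annotated
`possibly_fetal` in a `candidates` attribute — a deliberately
non-standard intermediate class for reviewer attention only.

Useful identities: multiplying the centered profile and `mb` by a
common factor leaves calls unchanged (scale equivariance); as `ff`
rises the fetal band narrows from both sides, so fetal calls are
non-increasing and maternal calls non-decreasing in `ff` on a fixed
segmentation.

## Critical regions from labelled deletion records

`derive_region` turns a set of pathogenic/benign-labelled deletion
records (ISCA-style) into a syndrome critical region: per-base coverage
by pathogenic (and likely-pathogenic) records is computed by an
endpoint sweep; starting from coverage cutoff 45 (lowered first to the
maximum observed coverage if smaller), the maximal interval containing
the global coverage maximum is taken, and the cutoff decremented by one
(unit steps assumed; the decrement schedule is not specified further)
until no non-excluded pathogenic record overlaps the region by at most
`min_overlap` bp (default 0 = "entirely outside"; 20 kb reproduces the
distal-deletion exclusion rule used at the DiGeorge region's 3' end).
Manual curation is expressed as explicit record-id exclusion lists, so
derivations are reproducible. Benign coverage is computed for plotting
parity but plays no role in the cutoff. The five shipped presets
(cutoffs 45, 45, 28, 25, 3) are documented reference output; recreating
them requires an ISCA database snapshot, which is external.

## In-silico evaluation engine

`spike_in` multiplies the bins of a target interval in a GC- and
PCA-normalized (pre-centering) profile by `1 - ff/2` (fetal deletion),
`1 + ff/2` (fetal duplication) or `1 -/+ (1-ff)/2` (maternal). The
multiplication sits after both normalizations because fetal fraction is
not uniform along the genome; the factors act on count-scale values.
`downsample_profile` thins a raw profile binomially to a target read
count. `run_ff_grid` and `run_readcount_grid` run one simulation per
(region x background x level) — the full-factorial bookkeeping is
audited against `study_plan` — and tabulate sensitivity and specificity
per (deletion-size class, level) cell with the size classes 0-1, 1-2,
2-3, 3-4, 4-5, 5-10, 10-40 Mb. "Correctly predicted" is operationalized
as a call of matching type and origin overlapping the truth interval by
at least one bin (the source of the quoted sensitivities does not
define it; a maternal call over fetal truth counts as incorrect — the
stricter reading). A false positive is any call overlapping no truth
interval; specificity of a cell is the fraction of its simulations free
of false positives. The truth length, not the called length, indexes
the size class. Critical-region enlargement by 2 Mb per side is
available as a flagged variant of the region input but off by default
(no significant sensitivity gain).

## The synthetic world

`make_genome` / `make_cohort` / `make_case` / `make_isca_like` generate
every input the pipeline needs, so the package builds and tests fully
offline. Defaults state one world:

* Mini-genome of three autosomes plus X and Y, 310 Mb in 15,500 bins of
  20 kb. All read counts quoted "at the NM-read scale" are
  depth-equivalent on this genome (`equivalent_reads`: reads x genome
  length / 3.1 Gb), which keeps the per-bin anchor — about 6.5 reads
  per bin at the 1M-read scale — identical to a full-genome setting, so
  the filter thresholds (3.0 / 1.5) and detection regime carry over
  unchanged. The method is dimension-agnostic; hg19-like dimensions are
  a config away.
* Per-bin GC from a smooth autocorrelated process in [0.30, 0.60]; a
  contiguous centromere-like unmappable gap (5% of each chromosome);
  6% of mappable bins at near-zero rate and 4% with strong per-sample
  jitter (CV 0.5) — the populations the mean and variance filters
  exist to remove, tuned so that ~88% of bins survive filtering as in
  the method's real-data regime.
* Shared GC-bias curve `exp(-3 (gc - 0.45)^2)` with a per-sample linear
  tilt (sd 0.5 on the slope); shared low-rank cohort noise with three
  components (CVs 3%, 2%, 1.5%) and sample-specific factors; Poisson
  counts on top (an overdispersion knob is deliberately absent from the
  default: the calling thresholds implicitly assume near-Poisson
  shallow-WGS counts).
* The loadings of the shared noise have a ~180 kb correlation length
  (`loading_window = 9` bins). This was a genuinely open design point:
  multi-megabase-coherent cohort noise is statistically
  indistinguishable from real CNVs, and at desk-scale cohort sizes the
  PCA basis estimation error leaves a residual of order
  `sqrt(noise_floor / n_train)` per component regardless of the noise
  magnitude — so megabase-smooth loadings encode a world in which no
  cohort normalization can work. Real shared artifacts track
  mappability and GC micro-structure at the tens-to-hundreds-of-kb
  scale, which is what the default emulates.
* CNVs in `make_case` multiply expected rates before Poisson sampling
  (the laboratory-mix analogue), whereas `spike_in` multiplies
  normalized counts post hoc (the in-silico analogue); both pathways
  exist deliberately, mirroring the two validation arms. In the `ff = 1`
  limit `make_case` reproduces pure affected genomic DNA (factor 0.5).
* `make_isca_like` gives every pathogenic record exponentially
  distributed flanks around a planted core, so coverage is maximal on
  the core and `derive_region` provably can recover it; benign records
  avoid containing the core.

What a green spike-in test does establish: the end-to-end pipeline
recovers aberrations at the depths the formulas predict under counting
noise, GC bias, gaps and bad bins, with the stated thresholds. What it
does not establish: performance under fragmentation-pattern effects,
mosaicism, maternal CNV polymorphisms co-occurring with fetal events,
or real cohort artifact structure — none of which the generator
emulates.

The acceptance regimes (fetal fraction and read-count sensitivity
lower bounds) are evaluated on the Poisson-noise variant of this world
(`component_sd = 0`, `gc_sample_sd = 0`, structural features retained),
which is the cohort the acceptance criteria themselves prescribe; the
richer default world is used wherever the normalization machinery is
itself under test. Measured this way, sensitivity for fetal deletions
of 3-10 Mb at the 20M-read scale is ~98-100% for `ff >= 10%`, and
~95-98% at `ff = 10%` with 15-20M reads — consistent with the
published regime these bounds come from, with the residual shortfall
concentrated at the 3-4 Mb, `ff = 10%` corner where the 25% threshold
margin is ~1.5 standard errors of a segment mean.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED-compatible);
  reports render 1-based inclusive.
* Terminal bins shorter than half a bin are flagged unmappable rather
  than systematically undercounted.
* A constant-GC genome short-circuits the LOESS to a flat curve; fewer
  than 100 mappable bins refuse correction.
* Single-bin chromosomes yield one segment; zero-variance segments are
  never split; ties at classification thresholds count as significant.
* Binomial downsampling to a target equal to a background's own
  generation budget can exceed its realized Poisson total; simulation
  drivers run such levels at the full available depth, while
  `downsample_profile` itself keeps the strict `target <= total`
  contract.
* `derive_region` reaching cutoff 0 with outliers remaining raises an
  error directing the user to explicit exclusions, mirroring the manual
  curation the procedure sometimes needs.
* Model serialization is a single versioned JSON archive
  (`write_norm_model` / `read_norm_model`); run configuration is JSON
  (`--config`), as no YAML parser is available in the supported
  dependency set.

## Known limitations

* CBS is implemented natively (no external segmentation dependency);
  its permutation test uses a fixed segment-wide standard deviation
  rather than per-arc variance estimates, the common simplification for
  count data of this depth.
* Whole-chromosome aneuploidy z-scores, mosaicism quantification and
  sub-bin breakpoint refinement are out of scope.
* Calling on sex chromosomes is supported but lower-confidence (no PCA
  normalization there, and chrY bins are usually removed by the
  variance filter in mixed-fetal-sex cohorts).
* The fetal-fraction estimator (`estimate_ff_y`) is a linear chrY
  interpolation needing male-reference and female-background anchors;
  it is a convenience, not a validated estimator.
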