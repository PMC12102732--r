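---
title: "Merging and filtering multipass cIM peptide maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging and filtering multipass cIM peptide maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimmerge)
```

## The procedure

`cimmerge` operates on per-replicate peptide-identification tables produced
by a data-independent-acquisition search engine after ion-mobility-assisted
peak detection. For multipass cyclic ion-mobility (cIM) data the peak
detector must be told how wide to smooth: a *trendline* gives the assumed
ion-mobility peak FWHM (in drift-time bins) at DT bin 0 and DT bin 200, and
the engine is run once per candidate trendline. The package models the
trendline as a straight line between those two anchors. Only the anchors are
defined by the notation; we interpolate linearly because the auto-calculated
trendline used for single-pass data comes from a linear regression, so a
line is the faithful family. Outside the 200-push acquisition window the
line is clamped to its boundary value — DT bins beyond the window are not
physically meaningful, so extrapolation would only amplify noise.

The merge-and-filter pipeline runs in a fixed stage order:

1. **Replicate merge** within one trendline. Records are grouped by the
   identity key *(protein, sequence, modification)*. Charge states collapse
   into one key: the goal is one record per peptide *sequence*, and the
   modification field is kept in the key so that otherwise identical
   sequences with different modifications stay distinct. If one replicate
   reports a key more than once, its highest-scoring instance represents
   that replicate; the engine occasionally emits near-duplicate rows and the
   top-scoring one is the one a curator would keep.
2. **Replicate-count and RT-RSD filters.** A peptide must be seen in at
   least `min_replicates` distinct replicates, and the relative standard
   deviation of its retention time across the per-replicate representatives
   (100·sd/mean, sample SD with *n − 1*) must not exceed `max_rt_rsd`. A
   singleton returns RT-RSD 0 by convention, so singletons are governed by
   the replicate-count rule rather than by an undefined spread.
3. **Metric averaging and thresholds.** All remaining metrics are averaged
   arithmetically across the representatives; the mass error is averaged on
   its absolute value, since a signed mean could hide large alternating
   errors. The averaged record must pass every metric threshold; all
   comparisons are inclusive (≥ / ≤), so a threshold states the worst
   acceptable value.
4. **Rank and deduplicate.** Records are sorted by PLGS score (descending)
   and one record is kept per identity key. Ties are broken by higher
   summed product-ion intensity, then smaller absolute ppm error, then the
   lexicographic key — a deterministic order, so the pipeline is invariant
   to input row order. The survivor's `source_tags` field accumulates the
   union of the trendline tags it was seen under, preserving provenance
   through pooling.

Two pooling modes reuse stages 3–4 on concatenated inputs: *multi-sequence*
(single-pass + best multipass trendline) and *multi-trendline* (every
trendline). Since stage-3 metrics are computed per trendline before
pooling, the pooled unique-key set is exactly the union of the per-trendline
filtered sets; the test suite checks this union law against a brute-force
set-union oracle on hundreds of random instances, along with filter
monotonicity (tightening any threshold never adds a survivor) and
deduplication idempotence.

**Best-trendline selection** applies the full pipeline per trendline and
picks the tag with the most unique peptides. An exact tie goes to the
smaller `fwhm_start` anchor: of two equally productive trendlines the one
applying less smoothing runs the smaller risk of merging distinct
ion-mobility features.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `min_replicates` | count | 2 | a peptide seen once is not reproducible enough to track under deuteration |
| `max_rt_rsd` | % | 5 | chromatographic stability needed for RT-based precursor matching |
| `min_products_per_aa` | ions/residue | 0.2 | fragment evidence spread along the backbone |
| `min_intensity` | counts | 5000 | weak precursors give unreliable deuterium centroids |
| `min_length` / `max_length` | residues | 4 / 30 | shorter peptides carry little exchange information; longer ones resolve poorly |
| `min_matched_products` | ions | 3 | minimum fragment support for the identification |
| `min_consecutive_products` | ions | 2 | contiguous ladder support |
| `min_sum_product_intensity` | counts | 500 | aggregate fragment signal |
| `min_plgs_score` | score | 6.62 | search-engine confidence floor |
| `max_abs_ppm_error` | ppm | 10 | precursor mass accuracy |

These defaults are a field-typical profile, shipped as an editable YAML file
(`inst/extdata/default_thresholds.yaml`); the optimal values are
instrument- and protein-dependent and published profiles for this workflow
are not printed anywhere we could transcribe them from, so the defaults are
a starting point, not a calibration.

## What the simulator emulates — and what it does not

The built-in processing backend replaces the proprietary peak-detection and
database-search engine with a generative model:

* **Digestion**: nonspecific (pepsin-like) fragmentation is modelled as
  uniformly sampled subsequences (default lengths 5–20, density 2–2.5
  sampled peptides per residue), not as cleavage-preference tables. This
  reproduces the overlapping, redundant peptide ladders HDX maps rely on,
  which is what the downstream metrics consume.
* **Wrap-around**: each true peptide gets a periodic drift time; its
  multipass DT bin is `(periodic_dt * n_passes) mod 200` (default 6
  passes). The multipass peak FWHM is drawn from a two-component mixture
  (defaults: means 12 and 22 bins, SD 1.5) standing in for ion populations
  whose widths respond differently under multipass separation; single-pass
  FWHM comes from one narrow unwrapped component (mean 6, SD 1).
* **Detection**: under trendline `t` at DT bin `d` a peptide is emitted with
  probability `p_max * exp(-(fwhm_at(t, d) - true_fwhm)^2 / (2 sigma^2))`
  (defaults `p_max` 0.97, `sigma` 2 bins). The Gaussian mismatch kernel is
  this package's own model of the qualitative mechanism — under- and
  over-smoothing both lose identifications — and its parameters are
  config-exposed, not measured constants.
* **Noise**: per-replicate jitter on retention time (SD 0.05 min), score
  (SD 0.3), intensities (log-normal, 10%), ppm error (SD 0.5).
* **False positives**: one decoy per filter rule, each violating exactly its
  rule with a wide margin while passing all others (the replicate-count
  decoy appears in a single replicate; the RT-RSD decoy receives 2 min RT
  jitter). This makes filter efficacy testable rule by rule.

All randomness fans out deterministically from one user seed to sub-streams
per (trendline, replicate), so simulated folders are byte-reproducible.

The simulator does **not** generate raw ion-mobility spectra, isotopic
envelopes, fragment spectra or deuterated data, and its mixture parameters
are illustrative: a passing simulation shows the *bookkeeping* —
merging, filtering, pooling, scoring — is correct under a plausible
detection geometry, not that any particular instrument will show the same
detection rates. Conclusions about real data still require the real engine
behind the same folder contract.

## Numerical and interface choices

* Coordinates are 1-based inclusive; `end − start + 1` must equal the
  sequence length, and sequences are checked against the FASTA when one is
  supplied.
* The export dialect is an explicit, documented CSV schema
  (`peptide_columns()`) with a column-mapping argument so vendor exports
  with different headers can be adapted; it is not guaranteed bit-compatible
  with any vendor importer.
* `replicate_id` defaults to the file stem and `trendline_tag` to the parent
  folder name, matching the per-trendline folder convention (single-pass
  fixed at `1_1`).
* Final lists embed an ISO-8601 basic timestamp (`YYYYMMDDThhmmss`) in the
  filename.
* The auto-calculated single-pass trendline is fitted by ordinary least
  squares (the engine's internal regression flavour is unspecified; OLS is
  assumed) and clamped to a floor of 1 bin if an anchor comes out
  non-positive.
* Redundancy divides summed depth by *covered* residues by default — the
  average number of unique peptides covering each covered position — with
  the full-length denominator available as an option, since either
  convention appears in practice. Reports store unrounded values; rounding
  happens only at presentation.
* Degenerate inputs: empty replicate sets merge to an empty table (not an
  error); an empty final list still writes a header-only CSV; a coverage
  report with no peptides returns 0/0 by convention.

## Problem sizes

The test suite and the acceptance script run on synthetic targets of 120–160
residues with ~300–380 planted true peptides, 3 replicates, and 2 multipass
trendlines plus single-pass — large enough that every filter rule fires and
the union law is non-trivial, while a full run stays in the tens of seconds.

## Known limitations

* The real vendor engine is driven only via the emitted batch plan; invoking
  it is out of scope, as are spectral curation, deuterium-uptake calculation
  and decoy-database FDR estimation (the workflow relies on threshold
  filtering plus downstream manual curation).
* Periodic-DT "unwrapping" (re-linearising DT vs FWHM from combined zero-,
  single- and multipass runs) is not modelled beyond the simulator's
  wrap-around generator.
* The detection mixture is qualitative; precision/recall figures from the
  simulator characterise the pipeline, not an instrument.
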