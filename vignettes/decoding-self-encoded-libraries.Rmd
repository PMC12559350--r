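---
title: "Decoding self-encoded small-molecule libraries from tandem MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding self-encoded small-molecule libraries from tandem MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selms)
```

## The decoding problem

A self-encoded library (SEL) is a combinatorial small-molecule library whose
members carry no identification tag: every compound is a tuple of building
blocks (BBs) assembled on a known scaffold, and its identity is recovered
from its own tandem-MS fragmentation. After an affinity selection — panning
the pooled library against an immobilized target, washing, and eluting — the
retained compounds are measured by LC-MS/MS, and the decoding task is to
decide, for each MS2 scan, which library member (if any) produced it.

Because the library is fully enumerable in silico, decoding reduces to three
steps, each implemented here as a composable, tibble-returning function:

1. **Enumerate**: the library is the cross product of the BB sets at each
   scaffold position. Each BB carries a *contribution formula* — the atoms it
   adds to the assembled molecule with condensation losses (e.g. $-\mathrm{H_2O}$
   per amide bond) already applied — so a member's molecular formula is the
   plain sum of its contributions plus a scaffold *offset formula* holding
   core/terminal atoms. Monoisotopic masses follow by summing standard
   atomic masses.
2. **Predict fragments**: a small grammar names the fragment ions expected
   from a scaffold. `S[i;j]` is the contiguous span of positions $i..j$
   (0-based) *plus* the scaffold offset; a bare integer $k$ is the BB at
   position $k$ alone. Each type is emitted at hydrogen-shift variants
   $h \in \{-H,\dots,+H\}$ (±1.0078250 Da per unit) and ionized with the
   configured adduct (default $[M+H]^+$, +1.00728 Da, charge 1).
3. **Filter and annotate**: an MS2 scan is retained iff its precursor
   neutral mass $(m/z - m_{adduct}) \cdot z$ matches a library mass within
   the MS1 tolerance *and* at least `min_matching_peaks` of its
   `n_considered_peaks` most intense peaks lie within the MS2 tolerance of
   the candidate's predicted ions. All ppm computations use the theoretical
   mass as reference: $|\Delta m| / m_{ref} \times 10^6$.

Ahead of the filter, **background subtraction** removes sample features (and
their dependent MS2 scans) that also occur in bead-only control runs — the
unspecific binders. A sample feature is removed iff a control feature lies
within the m/z and RT tolerances and the sample/control intensity ratio is
*below* the cutoff; genuinely enriched features (high ratio) survive. With
multiple controls, matching any control suffices; a zero control intensity
gives an infinite ratio (kept).

## Default parameters

All defaults reproduce the standard workflow settings and are plain
arguments:

| parameter | default | meaning |
|---|---|---|
| `ms1_ppm` | 5 | precursor mass tolerance (ppm) |
| `ms2_ppm` | 5 | fragment mass tolerance (ppm) |
| `n_considered_peaks` | 5 | top-N MS2 peaks examined |
| `min_matching_peaks` | 1 | matched peaks required to retain a scan |
| `hydrogen_shifts` | 1 | shift variants −1, 0, +1 per fragment type |
| `adduct` | `[M+H]+` | singly protonated positive ions |
| `rt_tol_s` | 10 | RT tolerance for background matching (s) |
| `max_intensity_ratio` | 3 | background removal below this sample/control ratio |

Two parameterizations of background subtraction circulate for this workflow
(10 s / 3-fold, and a stricter 2 s / 2-fold variant); we default to the
former, and both are one-argument changes. The `S[i:j]` colon form is
accepted as an alias of `S[i;j]`.

Counting matched peaks uses *distinct peaks*, assigned greedily to predicted
ions by ascending ppm error with each peak and each ion used at most once
(whether "matching peaks" counts peaks or predicted ions is ambiguous; we
chose peaks and expose the machinery so either is recomputable). Isobaric
candidates that pass the filter are ranked by an intensity-weighted coverage
score: the summed intensity of matched top-N peaks over the total top-N
intensity, plus a $10^{-6} \cdot n_{matched}$ tie-nudge, clipped to $[0,1]$;
remaining ties break deterministically by compound id. This transparent
score replaces fingerprint-based re-ranking deliberately: it is exactly
recomputable and needs no trained model. The rank-1 candidate of a retained
scan is the *accepted* annotation; per-compound hits deduplicate accepted
scans by compound id.

## Enrichment statistics

For a selection, the enrichment is the binder fraction after selection over
the binder fraction in the library:

$$E = \frac{\#\text{found binders} / \#\text{compounds after selection}}
           {\#\text{total binders} / \#\text{total library}}$$

Since the true binder count is unknown, the *maximum enrichment* postulates
total binders = found binders, reducing $E$ to library size over compounds
after selection. `max_enrichment(74, 228, total_library = 499720)` gives
2191.75, i.e. $2.2 \times 10^3$ at two significant figures; the statistic is
invariant under scaling both library counts.

Per-building-block enrichment uses the one-sided hypergeometric upper tail:
drawing `hits_total` distinct compounds from the library, the probability of
seeing at least `hits_with_bb` members containing the block. The 2×2 table is
*hits containing the BB vs not* against *library compounds containing the BB
vs not*, tested per position (the natural reading of block-level enrichment;
the construction is an argument, not a constant). p-values are computed via
`phyper(log.p = TRUE)` so tails far below the double-precision underflow
limit keep a finite `log10_p`, and Benjamini–Hochberg q-values are attached
because a report tests one block per position per set — typically hundreds.

## The synthetic-data generator

`simulate_experiment()` produces a ground-truthed sample/control pair with
the statistical structure the decoder assumes:

* each **binder** gets an MS1 feature at its adduct m/z (Gaussian relative
  jitter, `ppm_jitter_sd`), a uniform retention time in `rt_window_s`
  (default 60–1800 s, a typical nano-LC gradient), log-normal intensity, and
  one MS2 scan per feature by default (data-dependent acquisition is
  sparse); its peaks are the predicted fragment ions, with one emission
  decision per fragment *type* (an emitted type contributes all its
  hydrogen-shift variants, so observed per-type frequencies estimate the
  emission probabilities directly), plus Poisson noise peaks;
* **noise scans** get precursors rejection-sampled at least
  `decoy_offset_ppm` (default 50 ppm) from every library mass, so the
  false-positive channel isolates MS2-level failures;
* **background features** appear in both runs at the same m/z and RT with a
  sample/control intensity ratio drawn from `background_ratio_range`
  (default 0.5–2.5, below the 3-fold cutoff, i.e. removable background).

Everything is driven by one seed; the same seed reproduces byte-identical
mzML payloads and truth tables. The generator does *not* model
chromatographic peak shape, isotope envelopes, charge states above 1, or
inter-run RT drift — so a perfect score here shows the decoding logic is
correct under its stated assumptions, not that the pipeline is robust to
every property of real data.

`estimate_fragmentation_frequencies()` closes the loop: given spectra of
known compounds it reports, per fragment type, the fraction of spectra
containing a matching peak — the empirical basis for choosing a scaffold's
fragment grammar.

## Numerical and design choices

* **Formula arithmetic** uses named integer count vectors; signed counts are
  legal internally (condensation bookkeeping) but a fragment whose shifted
  formula would go negative is skipped with a warning. Predicted ion lists
  are sorted and deduplicated within $10^{-6}$ Da.
* **Mass windows** on the sorted library index are closed intervals
  $[m/(1+\delta),\ m/(1-\delta)]$ with $\delta = \mathrm{ppm} \times 10^{-6}$,
  which is exactly the set a linear scan returns (tested against one).
* **Feature finding** is deliberately simple — single-linkage chaining of
  MS1 peaks within 5 ppm and a 6 s RT gap, apex = maximum intensity — and
  can be bypassed entirely with a sidecar feature TSV.
* **Mass degeneracy** groups compounds by single-linkage chaining on sorted
  masses at a ppm threshold; members of a group are indistinguishable at
  MS1 and resolvable only by fragments. Compounds that also share a fragment
  set within tolerance are indistinguishable *in principle*; recall claims
  for clean data therefore apply to mass- or fragment-resolvable members,
  which real designs maximize by construction.
* **BB ranking for library design** scores each virtual member 0–5 by
  Lipinski parameters (MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10,
  TPSA ≤ 140 Å²; configurable, since published cut-offs vary) and
  aggregates the **mean** points over members containing each block — means,
  not sums, keep positions with different set sizes comparable (`statistic =
  "sum"` is available). Scoring a billion-member virtual library does not
  require materializing it: `rank_building_blocks()` accepts any member
  sample, and full enumeration is capped at $10^7$ members. Descriptors come
  from the BB table, or from SMILES via ChemmineR/ChemmineOB when installed.
* **Problem sizes in the test suite** are chosen for sharp oracles at
  desk scale: oracle-equivalence suites run on libraries of 27–216 members
  where brute force is exact; the enumeration check runs the four published
  design cardinalities (up to 499,720 members, seconds of runtime); and
  simulation-based properties use 300–600 scans where binomial 3σ bounds
  are tight enough to detect real defects.

## Known limitations

* The annotator assumes centroided, singly charged, positive-mode data; no
  isotope-pattern or charge-state deconvolution is attempted.
* No RT alignment between sample and control runs — the RT tolerance must
  absorb drift.
* The candidate score is fragment coverage, not a probabilistic match model;
  on heavily degenerate libraries the accepted-candidate error rate is
  bounded by mass degeneracy, which `mass_degeneracy()` quantifies per
  design.
* Hit calling is per compound; no motif or pharmacophore interpretation of
  enriched building blocks is provided.
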