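---
title: "Consensus mass fingerprints: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus mass fingerprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superspectra)
```

## The identification model

Protein profiling by linear-mode MALDI-TOF mass spectrometry reduces a
whole-organism (or organ) spectrum to a *peak list*: the masses of singly
charged protein ions, typically between 2 and 20 kDa. Species
identification then becomes a set-matching problem. For each species a
consensus set of biomarker masses — a *superspectrum* — is built from
replicate spectra of several reference specimens, and an unknown spectrum
is called as species $s$ when the fraction of $s$'s biomarkers that the
query reproduces within a relative mass tolerance reaches a threshold:

$$
\mathrm{match}(q, s) \;=\; \frac{\#\{\,b \in B_s : \exists\, m \in q,\;
|m - b| \le t \cdot \tfrac{m+b}{2}\,\}}{|B_s|} \;\ge\; \theta ,
$$

with $B_s$ the biomarker set, $t$ the relative tolerance and $\theta$ the
identification threshold. Matching is *injective*: a biomarker counts at
most once and a query mass may satisfy at most one biomarker, so a single
broad peak cannot cover two nearby reference masses. On sorted lists the
admissible partners of each mass form a contiguous, monotonically
shifting run (a convex bipartite structure), so the left-to-right sweep
used by `match_masses()` attains the maximum possible match count; the
test suite verifies this against a brute-force bipartite matcher.
Intensities are deliberately ignored everywhere: only the presence or
absence of a mass is scored, which is what makes fingerprints comparable
across instruments with very different detector responses.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tolerance_ppm` | 800 | ppm | relative mass-matching window, $\approx$ 0.08 %, typical linear-TOF accuracy |
| `threshold` | 0.75 | fraction | minimum biomarker match fraction for an identification (inclusive) |
| `min_count` | 30 | masses | data-count quality gate; below it a spectrum is never identified |
| `consensus_fraction` | 0.75 | fraction | minimum support (fraction of replicate spectra) for a consensus biomarker (inclusive) |
| `mass_window` | 4000–20000 | Da | biomarker window for reference building |

Two boundary conventions matter and are fixed deliberately. The quality
gate is inclusive at the boundary: a spectrum with exactly 30 evaluable
masses is *high* quality ("fewer than 30" is low). The identification
threshold is also inclusive, so a query matching exactly 3 of 4
biomarkers (75 %) is identified — with a strict comparison that common
case would be undecidable.

The 800 ppm tolerance is a package default, not a measured instrument
property: commercial fingerprint-matching software does not publish its
window, and linear-mode external calibration is usually quoted in the
few-hundred-ppm range. It is wide enough to absorb a ~300 ppm systematic
cross-instrument calibration offset on top of ~200 ppm random jitter,
and narrow enough that biomarkers of unrelated proteins rarely collide.

## Reference construction

`build_superspectrum()` pools all replicate spectra of a species' training
specimens and bins the pooled, sorted masses by **single-linkage
agglomeration**: consecutive masses join one bin when their gap is at most
`tolerance_ppm` of their midpoint. Single linkage over the pooled sorted
list is deterministic, independent of specimen and replicate order, and
avoids the boundary-splitting artefacts of fixed-width grids (a peak
cloud straddling a grid edge would be split in two). A bin's *support* is
the number of distinct spectra contributing at least one mass; the bin
becomes a biomarker when support reaches `consensus_fraction` of all
replicate spectra and its representative mass (the arithmetic mean of the
members — order-free, and with $\le 20$ contributors indistinguishable
from the median) lies inside the mass window. The builder *refuses*
low-quality replicates instead of silently dropping them: a reference
database should only ever contain spectra that pass the quality gate, and
an explicit error surfaces contaminated training sets. The model-level
wrapper `build_reference()` applies a softer policy across species:
specimens with low-quality replicates are excluded and reported, and a
species is dropped (with a report entry) only when too few specimens
survive.

The consensus rule — support fraction over *all* pooled replicate
spectra, inclusive at the boundary — is the simplest rule consistent with
independently built references (e.g. from colony versus field specimens
of one species) yielding identical biomarker lists; the proprietary tool
it stands in for does not document its algorithm.

## Replicate and specimen calls

Identification is hierarchical, mirroring how specimens are measured in
quadruplicate. Each replicate gets a call: `no_id_low_quality` (gate
failed), `identified` (best match fraction $\ge \theta$), or
`no_id_below_threshold`. Matches are ranked by fraction, ties by the
number of matched biomarkers, then species name; an exact tie is resolved
deterministically by name order but stays visible in the retained match
table rather than being hidden behind a special status. At specimen
level, the set $S$ of species called across replicates decides: one
species — `identified` (even when other replicates failed, since an
identification *was* produced); two or more — `discrepant`; none —
`no_id_low_quality` only if every replicate failed the gate, otherwise
`no_id_below_threshold`.

## Diagnostics

`sensitivity()` is the percentage of specimens whose call equals their
true (morphological/genetic) species, over all specimens or over
high-quality spectra only. `specificity()` is defined — following the
validation-study usage, not the epidemiological 2×2 definition — as 100
minus the percentage of wrong identifications; the denominator is either
the specimens that yielded an identification (the stated definition) or
all high-quality spectra (`denominator = "high_quality"`), because
published field-cohort figures divide by the latter. Percentages round
half-up at a caller-chosen precision since published studies mix integer
and one-decimal reporting. `ledger_from_counts()` reconstructs a
row-level truth-versus-call ledger from aggregate outcome counts, which
is how the acceptance script recomputes every published percentage from
the printed numbers rather than asserting them. `correct_mislabels()`
implements the audit step in which specimens whose spectrometric and
independent genetic identifications agree against the original label get
their truth rewritten, with the corrected ids recorded in an attribute.

## Cluster analysis

`dice_similarity()` scores two peak lists by the Dice coefficient
$2|M|/(|a|+|b|)$ on the injective tolerance-match set $M$; two empty
lists are identical by convention. `upgma()` implements the paired-group
algorithm by hand because its determinism is pinned down: ties at the
minimum distance merge the lexicographically smallest label pair, merge
height is $d/2$, and distances to a merged cluster are size-weighted
averages. The test suite cross-checks heights and cophenetic distances
against `stats::hclust(method = "average")`, which serves as the
independent oracle, never as the implementation. `to_newick()` emits
branch lengths as height differences so `ape::read.tree()` reproduces
the ultrametric tree exactly.

## The synthetic-data generator

No public repository of arthropod fingerprint spectra exists, so the
package ships a generator with known ground truth; its defaults are the
study conditions the pipeline targets.

* **Profiles.** Each of `n_species` species gets
  `biomarkers_per_species = 40` masses drawn uniformly in 3–20 kDa. The
  minimum pairwise separation is $2(t + 3\sigma_j)$ in relative terms
  (tolerance plus three jitter standard deviations, both sides): two
  jittered peak clouds any closer would occasionally be chained into one
  bin by single linkage, making reference builds irreproducible for
  reasons that have nothing to do with the consensus rule. This implies
  the weaker "separated by more than twice the tolerance" invariant.
* **Replicates.** Five specimens per species, four technical replicates
  each (the quadruplicate reference design). A biomarker is detected with
  probability `detect_prob = 0.95`, its observed mass is
  $m(1 + \varepsilon + \delta)$ with $\varepsilon \sim
  N(0, 200\,\mathrm{ppm})$ and $\delta$ the instrument calibration
  offset, and Poisson(5) uniform noise peaks are added before clipping to
  the instrument window (Bruker 2–25 kDa, Shimadzu 3–20 kDa).
* **Storage degradation.** Harsh storage (ethanol worse than deep
  freezing) empirically destroys the high-mass part of a profile while
  leaving low-mass biomarkers intact. The generator models this as an
  exponential detectability decay above a 10 kDa onset:
  $p = p_0 \exp(-\lambda \cdot \mathrm{sev} \cdot \max(0, m - M_0)/1000)$
  with $\lambda = 0.4$ per kDa. No quantitative decay data exist, so
  $\lambda$ was fixed once such that severity 1 visibly thins the
  high-mass half of a spectrum (a 15 kDa peak keeps 14 % of its
  detectability) without touching the sub-10-kDa range; severity 0
  represents fresh material, 0.5 is a deep-frozen-like condition and 2
  or more an ethanol-like one. Parameters are exposed, not fitted.
* **Randomness.** Every cohort draw seeds R's RNG once from the
  configuration seed; serialized cohorts are byte-identical across
  same-seed runs.

What the generator does *not* emulate: isotope envelopes, adducts,
intensity structure, correlated (batch) dropout, or mass-dependent
resolution. Passing tests on synthetic cohorts therefore demonstrate the
pipeline's arithmetic and its robustness to jitter, dropout, calibration
offsets and high-mass loss — not that any particular real taxon is
identifiable, which depends on how distinct its true biomarker sets are.

## Numerical choices and degenerate inputs

* Masses serialize at 4 decimal places (0.1 mDa, beyond any linear-TOF
  accuracy), so database round trips are lossless at stored precision.
* Exact duplicate masses collapse on read, keeping the larger intensity
  — deterministic and order-independent.
* Empty peak lists are valid everywhere: data count 0, low quality,
  match fraction 0, Dice distance 1 to any nonempty list.
* An empty consensus (no bin reaching support) is a valid, empty
  superspectrum; identification against it is refused explicitly.
* Percentages with empty denominators raise errors in the metric
  functions and surface as `NA` in `summary()`, never as silent zeros.
* Rounding is half away from zero, not banker's, to match how published
  percentages are printed.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
reference design scale: 8 species × 5 specimens × 4 replicates for
training, 20 held-out specimens per species for validation, 1000-instance
brute-force cross-checks for the binning/matching/UPGMA primitives, and
60-draw Monte-Carlo summaries per storage-severity level. These sizes
give stable results (the end-to-end accuracies are far from their
decision boundaries) while keeping a full run in the low tens of seconds
on one CPU.

## Known limitations

* The consensus rule and the matching tolerance are documented stand-ins
  for an undocumented commercial implementation; absolute agreement with
  that software on real exports is not claimed.
* With the default 5 % dropout, a biomarker's support across 20 replicate
  spectra occasionally (p ≈ 3×10⁻⁴ per biomarker) falls below the
  inclusive 75 % consensus boundary, so two independently rebuilt
  references can differ by a single biomarker; `rebuild_check()` is
  strict 1:1 and will report such pairs as different.
* `specificity()` implements two denominators because the published
  usage is itself inconsistent between cohorts; users must choose
  consciously.
* The mzXML reader supports only the exported mass-list dialect (one
  scan per replicate, uncompressed peaks); raw profile spectra, peak
  picking and vendor binary formats are out of scope.
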