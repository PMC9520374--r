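---
title: "Screening and annotating pathway metabolites with modification neutral losses and probe networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and annotating pathway metabolites with modification neutral losses and probe networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprobe)
```

## The model

pathprobe treats a pathway's post-modification chemistry as a mass
vocabulary. Each modification reaction (methylation, hexosylation, coniferyl
alcohol conjugation, ...) adds a fixed elemental composition to a substrate,
and under collision-induced dissociation that moiety is frequently ejected
as a neutral. Three consequences are exploited, in order:

1. **Screening.** A fragment at precursor − *m*(mod), within a relative mass
   window, is evidence that the metabolite carries that modification. The
   set of features with at least one such loss is the *modified metabolome*.
2. **Networking.** A modified analogue keeps much of its parent's fragment
   ladder, either at identical m/z (fragments not containing the modified
   site) or shifted by the precursor difference (fragments containing it).
   The modified cosine scores both pairings, so analogues cluster.
3. **Annotation.** Inside a cluster, an edge between an annotated node and
   an unannotated one whose precursor Δm/z equals a modification mass is
   read as "same scaffold ± that modification" — identity is propagated
   outward from seeds. Where no seed exists, fragment-level neutral losses
   and characteristic ions still name substructures, and combinations of
   those substructure masses that sum to the precursor give a de-novo
   composition hypothesis.

The assumptions worth stating: losses are neutral (so polarity only selects
the dataset, never the registry mass); a single MS/MS spectrum represents a
feature; in-source adducts and isotopologues are only handled to the extent
that ion fusion merges same-mass/same-RT redundancy; and a precursor delta
matching a modification mass is *circumstantial* — corroboration by the
neighbor's own neutral loss is recorded but, as in standard practice, not
required.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `ppm` | 15 | ppm | feature↔MS/MS precursor matching, neutral-loss matching, edge-delta matching, ion fusion |
| `rt_window_s` | 12 | s | feature↔MS/MS matching and ion fusion, as \|ΔRT\| ≤ 12 |
| `min_fragment_intensity` | 100 | abs. counts | fragments below this never witness a loss |
| `similarity_threshold` | 0.7 | – | minimum modified cosine per network edge |
| `min_matched_peaks` | 6 | – | minimum fragment pairs per edge |
| `precursor_merge_tol_da` | 0.01 | Da | node deduplication (spectral clustering) |
| `fragment_tol_da` | 0.02 | Da | fragment pairing in both similarity measures |
| `max_neighbors` | 50 | – | per-node edge cap (mutual top-K) |
| `max_component` | 500 | – | component size cap |
| `max_depth` | 3 | steps | propagation radius |

The first block mirrors the acquisition reality of a high-resolution
TOF workflow (≈ 5–15 ppm calibration accuracy, ≈ 12 s chromatographic peak
width); the network block is the conventional GNPS-style parameterization.
`max_depth = 3` is this package's own choice: each propagation step matches
a delta by mass alone, so confidence decays roughly geometrically with
depth, and three inferred modifications is where chains stop being
defensible without orthogonal evidence.

Mass-window convention: "15 ppm" is always relative to the *reference* mass
(the registry mass for delta matching, the feature m/z for precursor
matching), computed as `1e6·(observed − reference)/reference`.

## Numerical and procedural choices

* **Peak assignment.** The modified cosine requires a one-to-one pairing.
  The default is the exact maximum-weight bipartite matching over candidate
  pairs (direct or shifted), computed with igraph; a greedy-by-score variant
  exists for speed but the exact matcher is the contract — the test suite
  pins it to brute-force enumeration over all pairings on small spectra.
  Intensities are square-root transformed before unit normalization (the
  networking convention; plain intensities are selectable).
* **±2H adjustment.** Ring-opening chemistry can shift an observed loss by
  2 × 1.00782503 Da from the registry mass. Adjusted matches are opt-in and
  always labelled (`-2H`/`+2H`), never merged with exact matches: the
  adjustment is an inference, not a library fact.
* **One spectrum per feature.** Acquisitions with several collision
  energies yield multiple MS/MS per feature; the closest-RT spectrum is
  used (ties: closest m/z). No spectral merging — deterministic and simple,
  at the cost of occasionally picking the least informative energy.
* **Ion fusion** is single-linkage transitive closure over the "within both
  windows" relation, represented by the highest-intensity member (ties:
  lower m/z). Single linkage makes fusion idempotent and order-independent.
* **Node deduplication** (0.01 Da precursor tolerance) absorbs the
  lower-total-intensity twin, ties resolved lexicographically. The 0.01 Da
  tolerance plays its usual spectral-clustering role; edges themselves are
  defined by similarity.
* **Component splitting.** The reference implementation of the 500-node cap
  is not public; here oversized components shed their globally weakest edge
  (ties: fewer matched peaks, then lexicographic node ids), recomputing
  components after each removal. Documented stand-in, deterministic.
* **Propagation conflicts.** A node reachable from several seeds keeps the
  shallowest-depth annotation, then the higher incoming-edge similarity,
  then the lexicographically smallest seed; losing alternatives are kept in
  the evidence notes.
* **Library-match threshold.** No separate dereplication threshold is
  specified by the workflow this package follows; the network threshold
  (0.7) is reused, configurable.
* **De-novo composition search** enumerates multisets of at most three
  assigned substructure masses (registry losses after adjustment, plus
  characteristic ions) summing to the precursor within the ppm window.
  Three parts keeps the search exact and the combinatorics honest; larger
  assemblies would mostly fit by chance.
* **Degenerate inputs.** Empty feature tables and empty registries warn and
  propagate empty results; empty spectra are errors at similarity time
  (there is no meaningful similarity involving zero peaks).

## The synthetic world

`generate_probes()` + `derive_modified()` + `add_noise()` emulate the data
shapes the pipeline consumes, with full ground truth:

* probes: distinct precursors over m/z 250–800, uniform random fragments,
  class labels from a fixed phenylpropanoid-subclass list, RT uniform over
  a 0–1500 s gradient (a typical 25–30 min run);
* derivatives: precursor = parent + Σ modification masses (drawn from the
  registry; a parent + chain combination is one metabolite and is never
  emitted twice), a stated fraction (default 0.8) of the parent's strongest
  fragments retained, and one exact planted fragment at precursor − mass
  per chain modification, so every planted loss is detectable at
  arbitrarily tight tolerance in the noise-free world;
* noise: random extra peaks, plus a **per-spectrum systematic m/z offset**
  (uniform within ±5 ppm by default) applied multiplicatively to the
  precursor and all fragments. This models calibration drift, the dominant
  error mode of TOF instruments, and preserves the empirical fact that
  within-spectrum mass *differences* are far more accurate than absolute
  masses — the property neutral-loss screening relies on. Feature-table
  m/z gets an independent offset (MS1 and MS2 are separate measurements)
  and RT jitter; decoy feature/spectrum pairs carry no planted losses.

What the generator does **not** emulate: chromatographic peak shapes,
isotope patterns, adduct series, co-fragmentation chimera spectra, and
intensity-dependent mass error. A green recovery test therefore establishes
that the pipeline logic is faithful (tolerances applied on the right
quantities, bookkeeping exact, recall bounded below under realistic
calibration noise) — not that real maize-leaf data would yield any
particular count.

One wrinkle surfaced by the generator: the registry legitimately contains
isobaric entries (e.g. syringyl alcohol and non-condensed caffeyl alcohol,
both C9H10O3). Mass-based matching cannot distinguish them; all matching
names are reported at screening time, and chain-level ground-truth checks
compare masses, not names.

## Known limitations

* Modifications are mass/formula objects; no structure-aware chemistry, so
  positional isomers and isobaric registry entries are indistinguishable.
* Full structure assembly to a named compound (and database lookup) is out
  of scope; de-novo output is a substructure composition, not a structure.
* The screening count of "metabolites" is the number of distinct fused
  features with ≥ 1 hit; workflows that count per-hit will differ.
* Retention-time prediction, in-silico fragmentation and compound-class
  prediction — the orthogonal validation layer of the original workflow —
  are intentionally absent.
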