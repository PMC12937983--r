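---
title: "Quantifying nucleolar-stress phenotypes and G4-associated gene programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar-stress phenotypes and G4-associated gene programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleostress)
```

## Scope and model

Transcription-inhibiting stress (e.g. doxorubicin or actinomycin D)
reorganizes the nucleolus: fibrillarin (FBL), normally confined to the
dense fibrillar component, segregates into peripheral *nucleolar caps* on
NPM1-positive nucleoli, and in cells with compromised p53 function it
instead disperses into discrete *nucleoplasmic foci*.  This package
implements two connected procedures around that phenotype:

1. **Single-cell image quantification.**  From a three-channel field
   (DNA, NPM1, FBL) each cell is segmented, its NPM1-positive nucleoli
   are found, cap segments are measured on the nucleolar rim, and
   nucleoplasmic FBL foci are counted.  Cells are classified by two
   independent rules: *cap-positive* (at least one qualifying rim
   segment, with nucleolar FBL at least as bright on average as
   nucleoplasmic FBL, in a cell that has an NPM1-positive nucleolus) and
   *nucleoplasmic-FBL-positive* (at least five nucleoplasmic foci).
   Proportions are reported over cells with an NPM1-positive nucleolus,
   per replicate, with mean and SD across replicates.
2. **Gene-program inference.**  Intersection-defined gene sets (genes up
   in the p53-deficient stressed condition and down on FBL knockdown,
   minus FBL itself; then the subset also down on CK2α knockout),
   promoter-proximal G-quadruplex annotation (TSS ± flank windows
   overlapped with BED interval collections under an
   at-least-one-collection rule), transcription-factor target annotation,
   interactome convergence across three protein sets, a hypergeometric
   over-representation test with Benjamini–Hochberg adjustment, Welch's
   two-sided t-test with conventional significance stars, and
   2^(−ΔΔCt) relative qPCR quantification.

Because the original image data and list derivations live in external
repositories, the package ships a first-class synthetic-data generator
whose outputs carry exact ground truth; every analysis stage is validated
by planted-truth recovery.

## The imaging pipeline and its parameters

All tunables live in one object, `quant_params()`.  Length units are
micrometres unless the name ends in `_px`; intensities are on a [0, 1]
working scale (16-bit on disk).

* `min_nucleus_area_um2 = 20` — discards segmentation debris; real
  interphase nuclei are far larger.
* `watershed_tolerance_px = 3` — seed depth for the distance-transform
  watershed that splits touching nuclei.  At the default tolerance of the
  underlying implementation, discrete ridges of the distance map
  over-fragment elongated nuclei; 3 px is deep enough to ignore ridge
  noise yet shallow enough to separate two overlapping ellipses whose
  centres are a nucleus radius apart.
* `rim_width_px = 3` — half-width of the annular band around each
  nucleolus boundary searched for cap segments.  Caps hug the rim;
  3 px (0.3 µm) covers boundary uncertainty from segmentation and blur.
* `mad_k = 3` — FBL-positive pixels are those above
  `median + 3·MAD` of in-nucleus FBL, a robust threshold insensitive to
  the bright minority of structured pixels.
* `min_cap_area_px = 5` — a qualifying cap must span at least 5 px.
  Rendered and real caps span hundreds of pixels at 0.1 µm/px; the floor
  exists solely so that isolated noise pixels that clear the intensity
  threshold can never count as caps.
* `enrichment_ratio = 1.5` — a rim segment is a cap only if its mean FBL
  is at least 1.5× the nucleoplasmic mean.  "Peripheral accumulation" has
  no published operational definition; this ratio separates genuine
  enrichment from the dim residual rim left after cap disruption.
* `exclusion_dilation_px = 2` — nucleoli are dilated by 2 px before being
  excluded from the focus search, so blur halos at the nucleolar edge are
  not counted as nucleoplasmic foci.
* `log_sigma_px = c(1.5, 4)` (step 0.5) — Laplacian-of-Gaussian scales
  for focus detection, spanning the radii of diffraction-limited puncta
  at 0.1 µm/px.
* `min_prominence = 0.1` — absolute floor on the LoG response of a
  reported focus.  On a clean image the robust (MAD-based) response
  threshold degenerates toward zero; the floor is set well above the
  response of the residual rim (≈ 0.01) and well below that of a real
  focus (≈ 0.4).
* `foci_threshold = 5` — positivity cutoff on the focus count ("≥ 5
  foci"), applied with `>=` so that 4 foci score negative and 5 positive.

Two deliberate interpretation choices, where the scoring rules are stated
verbally rather than operationally: *cap size* is measured as area in
µm² (pixel count × pixel-size²), and the nucleolar-versus-nucleoplasmic
intensity comparison uses **mean** intensities (integrated intensity
would conflate size with brightness).  A multi-nucleolus cell is
cap-positive if **any** nucleolus carries a qualifying cap, matching
per-cell scoring.  Cells without an NPM1-positive nucleolus are retained
in the per-cell table for audit but excluded from all proportions.

Coordinates are (row, column), 0-based only on disk (BED); masks are
labeled rasters.  Line profiles are sampled bilinearly at ≈ 1 px steps
and each channel is divided by its own maximum along the line; an
all-zero channel stays all-zero rather than dividing by zero.

## What the synthetic generator emulates — and what it does not

`generate_field()` renders 2-D single-plane fields at 0.1 µm/px with
16-bit-scaled intensities: DNA as filled ellipses (semi-axes 3.2–4 µm),
1–3 NPM1-bright circular nucleoli per nucleus (0.9–1.3 µm radius), and
FBL per phenotype — interior dots for intact cells, rim crescents
subtending 40–90° for cap-positive cells (the stress-induced cap), and a
dim residual rim plus 5–10 Gaussian puncta (σ 2–4 px) for cap-disrupted
cells.  Treated phenotypes additionally receive diffuse nucleoplasmic
NPM1.  Foci are placed at least 2 px outside any dilated nucleolus and
mutually separated, so the peripheral/nucleoplasmic distinction is
geometrically unambiguous at zero noise; Gaussians are truncated at 3σ so
"zero noise" means exactly zero background.  The noise model is
shot noise (Poisson at `poisson_scale = 500` photons per unit intensity),
Gaussian read noise (sd 0.01), a Gaussian point-spread blur (σ 0.8 px)
and a camera baseline (0.05) that keeps the background off the zero clip
— without it, robust MAD statistics degenerate.  The microscopy source
material does not report its noise or intensity distributions, so these
defaults are stated, not inferred.

Cap-disrupted cells are rendered with a single rounded nucleolus
(disrupted nucleoli typically coalesce), which also guarantees room for
the planted foci under the mutual-separation constraint.

The generator does **not** emulate: 3-D structure, realistic optics
beyond Gaussian blur, intensity heterogeneity within structures, cell
crowding with touching nuclei (nuclei are placed without overlap by
rejection sampling), mitotic figures, or staining artefacts.  Passing
planted-truth tests therefore demonstrates that the measurement rules are
implemented correctly and are robust to shot/read noise and blur — not
that the pipeline segments arbitrarily hard real images; on real data the
thresholds above are the knobs to revisit.

Gene-table, interval and protein-list generators plant their set
cardinalities exactly: `generate_deg_tables()` realizes
|A∩B| and |A∩B∩C| (the seed gene FBL is added *on top of* the planted
shared count, so the planted number is what survives the seed-gene
exclusion); `generate_g4_fixture()` lays genes out on synthetic
chromosomes with dead zones wider than any interval so a decoy can never
stray into a neighbouring promoter window; `generate_protein_sets()`
realizes the pairwise fraction and triple intersection, optionally
forcing the canonical five-protein triple (NPM1, HNRNPA1, NCL, FUS,
MAZ).  Symbols are synthetic (`G000001`, `P00001`, …) so nothing depends
on real annotation.  Every generator draws from a private RNG stream
seeded explicitly; identical seeds give byte-identical outputs.

## Numerical and interface choices

* Genomic intervals are 0-based half-open (BED native) everywhere;
  overlap is `a.start < b.end && b.start < a.end`.  The indexed overlap
  engine (interval trees via IRanges, after mapping half-open to 1-based
  closed coordinates) is checked against an O(n·m) brute-force oracle in
  the test suite.
* The promoter window is symmetric, `[max(0, TSS − flank), TSS + flank)`
  with `flank = 1000` bp by default; strand does not change the window.
  The TSS policy defaults to `most_upstream` (5′-most per gene: minimum
  coordinate on `+`, maximum on `−`); genes missing from the annotation
  are reported and excluded from the denominator.  Chromosome names match
  exactly, with an optional chr-prefix normalization toggle.
* The enrichment universe defaults to the union of all collection
  members and is overridable; the hypergeometric p is upper-tail,
  BH-adjusted across terms, with ties ordered by rich factor then term.
* Symbol harmonization trims, strips quotes, uppercases and applies an
  optional alias map (e.g. "hnRNP A1" → HNRNPA1); it is idempotent, and
  DEG loaders accept pre-filtered lists as the primary input (the
  thresholds behind published DEG lists are usually not recoverable, so
  re-derivation is offered only as a convenience).
* Welch's t statistic uses the textbook unequal-variance formula with
  Welch–Satterthwaite degrees of freedom and a two-sided p from the t
  distribution.  Degenerate input (both samples constant and equal)
  returns t = 0, p = 1 by convention; both samples constant but unequal
  is an error.  Stars use strict inequalities: `*` p < 0.05, `**`
  p < 0.01, `***` p < 0.001.  At three observations per group the
  Welch–Satterthwaite approximation is *conservative*: the empirical
  type-I error at α = 0.05 is ≈ 0.035 (identically so for this
  implementation and `stats::t.test`), approaching nominal by n = 10.
* Relative qPCR uses 2^(−ΔΔCt) with 100% assumed amplification
  efficiency (the efficiency-corrected model is out of scope).  Replicate
  folds are `2^(−ΔΔCt)`; the condition-level fold is `2^(−mean ΔΔCt)` —
  the geometric mean of replicate folds — which is exactly 1 for the
  control condition, whereas an arithmetic mean of folds would exceed 1
  by Jensen's inequality.  qPCR replicates are treated as independent.

## Problem sizes used in validation

The test suite and the acceptance script validate planted-truth recovery
on fields of 150 cells (mixture 20% intact / 20% cap-positive /
60% cap-disrupted, the scale of a typical scored sample of 140–160
cells), gene universes of 20,000 symbols with planted 630/135
intersections, 135-gene G4 fixtures with 92 planted positives across two
BED collections, 10,000-interval oracle comparisons, protein sets of
100/300/60 with a planted 56% overlap and five-member triple, and
10,000-replicate null simulations for the Welch test.

## Limitations

Segmentation quality on real confocal data is untested here by
construction; the two-channel proximity readout is a distance-threshold
fraction, not a pixel-wise colocalization coefficient; G4 annotation is
interval-based (no sequence-level quadruplex prediction); and
set-membership inference is symbol-based with no ortholog or identifier
mapping.  Reproducing published gene counts from the original public
accessions additionally depends on the genome annotation release and TSS
policy, which the sources do not state.
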