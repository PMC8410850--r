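---
title: "Methods: quantifying the anatomy and dynamics of a 5-TM receptor"
author: "tmanatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the anatomy and dynamics of a 5-TM receptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmanatomy)
```

## The scientific problem

CD47 is the immune system's only five-transmembrane (5-TM) receptor. Its
IgV-like extracellular domain (ECD) is the "don't eat me" marker read by
SIRPα on macrophages, and it sits on top of a five-helix transmembrane
bundle, connected by a short peptide linker (residues 114–120) whose
tryptophan and phenylalanine side chains (W118/F119) bury into the
extracellular loop region (ECLR). How rigidly that architecture holds the
ECD above the membrane — and how it can move — is quantified through a
small set of bespoke measurements: a membrane-frame ECD tilt angle, contact
and hydrogen-bond geometry around the loops, buried surface areas of the
core side chains, macrostate analysis of tilt time series from molecular
dynamics, peptide-level hydrogen–deuterium exchange (HDX-MS) uptake, and
clade-wise sequence conservation mapped onto the structure. This package
implements those measurements as reusable, tested operations.

## Coordinate model and conventions

Structures are plain atom tables plus one coordinate matrix per model
(`structure3d`). Three conventions hold everywhere:

* **Author (PDB) numbering only.** Every residue the analyses care about
  (W118, Y184, C245, …) is cited in author numbering, so no renumbering is
  ever performed. Chains with disordered, unmodelled stretches are simply
  missing those residues.
* **Altloc policy.** Alternate locations resolve to the highest-occupancy
  conformer; ties go to the first record in the file. This makes parsing
  deterministic.
* **Hydrogens, waters and HETATM records are retained on read but excluded
  from geometry** unless explicitly selected, so glycans and solvent never
  leak into SASA or contact measurements.

## The membrane frame and the ECD tilt metric

The bundle frame places the origin at the centre of mass of the backbone
atoms of the five TM helices (helix I 121–140, II 160–178, III 186–207,
IV 224–242, V 251–278) and takes the membrane normal as their first
principal axis. The principal axis is parameter-free and deterministic; its
sign is fixed by requiring the extracellular reference residue (E123) above
the intracellular one (V274). The ECD tilt is then the angle in
[0°, 90°] between the vector from the origin to the centre of mass of the
CA atoms of the β-hairpin tip residues 32–36 and the membrane plane at
z = 0. 90° is an ECD standing perpendicular to the membrane; 0° is an ECD
lying in the plane.

```{r tilt}
toy <- make_toy_receptor(tilt_deg = 80)
frame <- build_frame(toy$structure)
ecd_tilt(toy$structure, frame)
```

The principal-axis frame reproduces planted tilts to well under a degree on
the synthetic receptor across the whole [0°, 90°] range, and every frame
quantity (tilt, span, kink, contacts) is invariant under rigid motions of
the input — both properties are enforced by the test suite.

## Contacts, hydrogen bonds, salt bridges

Inter-segment contacts are heavy-atom pairs at or below a cutoff (default
3.5 Å, conventionally scanned over 3–5 Å), excluding pairs within the
target segment and covalently adjacent residues (|Δresidue| ≤ 1). The
implementation is checked against an exhaustive O(n²) pair scan and is
monotone in the cutoff.

Hydrogen bonds are scored on heavy-atom donor–acceptor distance alone
(window 2.2–3.5 Å) using a residue dictionary of donor and acceptor atoms.
No angular criterion is applied because crystal structures at moderate
resolution carry no hydrogens; the underlying data report distances only
(e.g. a tyrosine hydroxyl at 2.9 Å from a backbone carbonyl). Salt bridges
are Asp/Glu carboxylate-O to Lys/Arg/His N pairs with minimum distance
≤ 4 Å. The intracellular polar network operation restricts the hydrogen-bond
search to the side chains of a member set (defaults Q141, K145, H206, Q227,
Q264) and reports connected components.

## Surface areas and ring geometry

SASA is Shrake–Rupley sphere sampling with a fixed golden-section spiral
point set, which makes areas bit-stable across runs and platforms. Radii
are a small documented per-element set (C 1.70, N 1.55, O 1.52, S 1.80 Å)
with a 1.4 Å probe and 960 points per atom by default; 960 points agree
with a 20 000-point reference within 2 % (with an absolute floor of
~0.5 Å² for atoms whose accessible area is a few sample points). Buried
area of a residue set is SASA of those atoms extracted in isolation minus
SASA of the same atoms inside the full structure — the "buried side chain"
usage, not a chain–chain interface area. Note this definition counts
occlusion by covalent neighbours, so even a fully exposed mid-chain residue
registers ~35 Å² of burial; interpretation should always be relative to
that baseline.

Aromatic ring planes are least-squares planes through the six ring carbons
(Phe/Tyr), all nine indole atoms (Trp) or the five imidazole atoms (His);
the interplanar angle is folded into [0°, 90°], so an edge-to-face pair
reads as an intermediate angle (~45–90°). Folding makes the measurement
symmetric and independent of ring-normal orientation conventions.

## Hydrophobic core layers

A hydrophobic residue (A/V/L/I/M/F/W/P) on a TM helix is "core-facing"
when its side-chain centre of mass is nearer the bundle axis than its own
CA. Core-facing residues are clustered along the membrane normal by 1-D
single-linkage with a 3 Å gap threshold and numbered from the
extracellular side. The core-facing rule is a documented convention — the
underlying structural observation names layer members but not a
classification rule — so downstream counts (like "22 core side chains")
should be treated as approximate, not exact.

## Trajectory macrostates

For structural trajectories, each frame's TM backbone is superposed onto
the reference structure (Kabsch, no reflection) and the tilt is measured in
the reference's frame, making the series invariant to how frames were
stored. Deviation is defined as θ_ref − θ(t), so positive deviation means
tilted further toward the membrane than the reference. A centred 1-ns
rolling mean gives the smoothed trace.

Macrostates are a two-component Gaussian mixture fitted to the deviation
series by EM with 50 restarts initialised by k-means on the smoothed trace
under a fixed seed; the best-likelihood fit wins, and `"auto"` chooses
between one and two states by BIC. This replaces visual identification of
histogram peaks with a deterministic, documented estimator. The transition
time into the higher state is the first time the smoothed trace enters
within one state SD of that state's mean and stays for ≥ 10 ns; event
detectors (tyrosine switch, salt-bridge formation) use a 5 ns dwell. The
dwell times are deliberate artifact choices, exposed in the configuration,
since the source analyses state none.

```{r macro}
tr <- make_trajectory(state_means = c(17, 40), state_sds = c(6, 3),
                      transition_ns = 300, seed = 1)
ms <- find_macrostates(tilt_series(tr$table, theta_ref = 80))
c(ms$state_means, transition = ms$transition_time_ns)
```

## HDX-MS uptake

Percent deuterium uptake is 100 × mass shift / (maximum exchangeable
amides × D₂O fraction), with the maximum excluding the two N-terminal
residues of each peptide and prolines from position 3 onward, and a D₂O
fraction of 0.917 reflecting the incubation buffer. No back-exchange
correction is applied, matching how the source experiments were processed.
Replicates are summarised by mean and sample SD (n−1); differential tables
join strictly on (start, end, sequence, timepoint), so peptides altered by
a mutation naturally fall out of the comparison and are reported in a
separate "uncomparable" list rather than silently dropped — a construct
pair with no common peptides yields an explicit empty comparison.

## Sequence conservation

Absolute conservation of a reference position within a clade means every
clade member carries the identical residue in that alignment column, with
gaps counting as mismatch; adding sequences can only shrink the set.
Column-wise MSA semantics were chosen (over pairwise alignments) and are
documented as such. The 1–9 conservation bins are identity fractions
(over non-reference sequences) binned by ceiling(9 × fraction) — an
intentionally simple, reproducible stand-in for evolutionary-rate models,
preserving the conventional nine-colour scale for structure painting.
Pairwise global alignment uses Needleman–Wunsch with affine gaps (a run of
length L costs open + extend × L) under a named substitution matrix, and is
validated against exhaustive enumeration on short sequences.

## What the synthetic generators emulate — and what they do not

Every input class has a generator with known ground truth, so the full
pipeline is testable without downloads:

* `make_toy_receptor` builds ideal α-helices (1.5 Å rise, 100° twist,
  2.3 Å helix radius) on a pentagonal cross-section, numbered to the default
  segment map, with a rigid CA-only pseudo-ECD placed at an exact planted
  tilt. Helices are centred on the membrane mid-plane: aligning their
  extracellular ends instead would bias the bundle principal axis by
  several degrees (helix V is much longer than the others) and break tilt
  recovery. A consequence is that the toy's 123→274 span is ~25.5 Å rather
  than the ~32 Å of a real bundle whose helices all reach the bilayer
  boundaries; the span metric itself is validated on an ideal 22-residue
  helix (21 × 1.5 Å = 31.5 Å).
* `make_trajectory` draws Gaussian deviations about two state means with a
  hard transition time — the statistical skeleton of a two-macrostate tilt
  series, without any physics.
* `make_hdx_tables` inverts the uptake formula to plant mass shifts, plus
  replicate Gaussian noise.
* `make_msa` plants an exact invariant-column set; at mutation rate 1 every
  other column is guaranteed to differ in every derived sequence.

Passing recovery tests on these inputs demonstrates that the estimators are
correct and unbiased under their own model assumptions. It does not
demonstrate robustness to real-data pathologies — correlated MD noise,
slowly drifting baselines, HDX back-exchange, alignment errors — which the
generators deliberately do not model.

## Problem sizes, numerical choices, defaults

* Macrostate validation uses ten seeds × 10 000 frames (0.1 ns spacing,
  1 µs span), state means 17°/40°, SDs 6°/3°, transition at 300 ns — the
  regime the method is meant for. One fit takes well under a minute.
* EM restarts 50, seed fixed and configurable; component SDs floored at
  1e-3° to avoid the classic mixture singularity; BIC penalises 3k−1
  parameters.
* Superposition uses SVD with a determinant guard (no reflections) and
  warns on near-collinear references instead of failing.
* Kink angles fit each arm's axis to a 4-residue running-centroid smoothing
  of the CA trace; the raw principal axis of a short helical arc wobbles by
  ~5° with non-integer turn counts.
* All tunables (cutoffs, probe radius, windows, dwells, D₂O fraction) live
  in `default_config()` and round-trip through YAML.

## Known limitations

* Hydrogen bonds are distance-only; protonation states and geometry are not
  considered.
* The conservation bins are identity fractions, not evolutionary rates; they
  will overweight shallow clades relative to a phylogeny-aware model.
* Buried areas depend on the radius set; literature values computed with
  other programs (different radii) should be compared with ~10 % tolerance.
* The package analyses trajectories and tables; it does not run simulations,
  build membranes, or process raw mass spectra.
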