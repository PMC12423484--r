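---
title: "B-factor indices for structure prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{B-factor indices for structure prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfindex)
```

## The model

Crystallographic B-factors (temperature factors, Å²) summarize the
vibration and static disorder of each atom in a refined model. A binding
site whose atoms move little relative to the ligand they hold is a better
template for docking than one where the ligand is smeared across the
density. `bfindex` condenses this into two ratios. Let the *binding site*
at radius $r$ be the set of protein heavy atoms whose minimum Euclidean
distance to any ligand heavy atom is at most $r$, and write
$\mathrm{BF}_{BS}$, $\mathrm{BF}_L$, $\mathrm{BF}_P$ for the median atomic
B-factors of the binding site, ligand and protein. Then

$$\mathrm{LBI} = \frac{\mathrm{BF}_{BS}}{\mathrm{BF}_L}, \qquad
  \mathrm{PBI} = \frac{\mathrm{BF}_{BS}}{\mathrm{BF}_P}.$$

Both are dimensionless and invariant to rescaling all B-factors by a
common factor, so structures refined with different overall B conventions
remain comparable. Medians are used throughout because deposited
B-factors — particularly of small-molecule ligands — often contain
outliers; the suite checks this robustness explicitly (a site pool of
{10, 20, 90} yields $\mathrm{BF}_{BS} = 20$).

Assumptions worth keeping in mind: the indices trust the deposited
B-factors as-is (no per-structure normalization, no occupancy weighting),
so comparisons across very different refinement protocols carry that
caveat; and an NMR or otherwise B-factor-free model has no meaningful
index, which the CLI refuses outright.

## Atom selection

The computation is defined on a precise atom set, and the reader
implements exactly that set:

* **first model** of a multi-model file;
* **first alternate-location configuration**: blank-altloc atoms are
  always kept; among altloc-labelled duplicates of one atom identity
  (chain, residue number, insertion code, atom name) the first in file
  order wins. Occupancy is deliberately not consulted — this matches a
  naive per-atom retrieval and makes the rule idempotent;
* **heavy atoms only** (element H and D removed), for distances and
  medians alike;
* the *protein* pool is the polymer: ATOM records plus hetero-recorded
  standard residues such as MSE (selenomethionine is a polymer residue,
  not a ligand). Waters (HOH, WAT, DOD, D2O), ions and other hetero
  groups are never part of the binding site;
* when a chain filter is given, $\mathrm{BF}_P$ is the median over the
  selected chain(s), not the whole file — the natural reading of a
  single-chain analysis. The default is all protein chains.

Elements missing from columns 77–78 are inferred from atom names (digits
stripped; names starting with a digit are hydrogens; two-letter symbols
such as ZN or the calcium reading of "CA" are accepted only for hetero
atoms, since the polymer "CA" is an alpha carbon). Zero or negative
deposited B-factors are retained but counted and surfaced as a quality
warning; malformed records are skipped with a warning, never silently.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| site radius | 10 (profile 5, 10, 15, 20) | Å | 10 Å is the conventional single-radius choice; the profile brackets tight contact shells through pocket-plus-rim |
| minBAG | 0.1 | pBA log units | the gap at which ranking power gains most over unconstrained sampling |
| resampling replicates | 1000 | — | benchmark convention; percentile CIs stabilize well before this |
| eROCE α | 32.19 | — | places weight ≈ 0.2 at 5% FPR, focusing the metric on early enrichment |
| VS success | eROCE > 0.1 (strict) | — | comparable to EF1% > 5, EF5% > 3, EF10% > 2 on typical rankings |
| redocking success | RMSD < 2 (strict) | Å | the standard pose-prediction criterion |
| success bins | <25, 25–50, 50–75, 75–95, >95 | % of DSFs | a fraction of exactly 0.95 falls in the fourth bin (our convention, stated here) |

The binding-site boundary is closed (distance ≤ r): conventional, and of
measure zero on real coordinates.

## The minBAG resampler

Benchmark sets pair each target with few ligands of uneven affinity
spacing, which biases per-target rank correlations. The resampler instead
draws complexes target-agnostically under a minimum binding-affinity gap:
a uniform anchor on [2, 14] pBA; a grid from the anchor toward both ends
with step equal to minBAG; nearest-pBA record per grid point (ties to the
lowest index); a sweep in increasing pBA dropping any record closer than
minBAG to the last kept one; finally a uniform three-quarters (floor)
subsample, which counteracts the over-selection of marginal activity
values under a roughly normal affinity distribution. Replicates with
fewer than three survivors are redrawn (bounded retries). The gap
invariant — all consecutive selected pBA gaps ≥ minBAG — holds by
construction and is property-tested over randomized seeds, gaps and
datasets.

Design points that were genuinely open and are fixed here: the grid step
equals minBAG (the only reading consistent with realized mean gaps close
to the nominal value at small minBAG); the sweep keeps the first of any
too-close pair; confidence intervals are 2.5/97.5 percentiles of the
replicate statistics; and all randomness flows through R's seeded RNG, so
(seed, parameters) reproduces every run byte-for-byte.

## Screening metrics

eROCE averages $e^{-\alpha \cdot \mathrm{FPR}_i}$ over actives, with
$\mathrm{FPR}_i$ the fraction of decoys ranked strictly before active $i$;
decoys tied with it (detected only when scores are supplied) count half —
a deterministic, order-independent convention that matters little on the
effectively tie-free rankings the metrics were designed for. Bounds
$e^{-\alpha} \le \mathrm{eROCE} \le 1$ and monotonicity under upward swaps
are property-tested. The enrichment factor uses a top-$\lceil fN \rceil$
cutoff (rounding was unspecified; ceiling is the generous choice), giving
$\mathrm{EF}(1) = 1$ exactly for any ranking. Pairwise group comparisons
delegate to `stats::pairwise.wilcox.test` with Holm adjustment; pairs
involving groups of fewer than three values are reported not assessable.

## What the synthetic generator does and does not emulate

`make_synthetic_complex()` places a hetero ligand on a 0.3 Å shell at the
origin, "site" CA atoms inside an inner shell (default ≤ 4 Å) and "far"
CA atoms beyond an outer shell (default ≥ 25 Å), with user-chosen
B-factor assignments. For any radius between the shells, site membership
— hence all three medians, LBI and PBI — is known in closed form, and the
suite asserts exact agreement between `compute_bi()` and both the
closed form and an independent all-pairs/sort-based brute-force oracle.
Protein atoms are CA-only glycines on deterministic Fibonacci-sphere
directions (jitter only when seeded): the index computation never
inspects residue chemistry, so richer geometry would add nothing to the
test. What the generator does **not** emulate: realistic packing,
B-factor gradients within a shell, altloc disorder, multiple chains and
crystal contacts. Passing tests therefore demonstrate the correctness of
the computation, not the empirical usefulness of the indices on real
crystal structures — the latter rests on benchmark data the package can
consume but does not bundle.

Default generator conditions (ligand ~10 atoms, site ~20, far ~40, B
around 10–40 Å²) mirror the scale of a typical drug-like ligand and
pocket; test batteries use 1000 random fixtures of 13–35 atoms, 1000
random rankings of ≤ 90 entries, and resampling runs of 50–200 replicates
on 80–285 synthetic complexes — sizes at which every oracle comparison is
exact and the whole suite runs in well under a minute.

## Numerical choices and degenerate inputs

Distances are compared as squared distances against $r^2$ with no
tolerance; the closed boundary is tested on exactly representable
coordinates. Undefined indices (empty binding site, non-positive median
in a denominator) are `NA` with a machine-readable reason — never 0 or
infinity — and the algebraic identities
$\mathrm{LBI} \cdot \mathrm{BF}_L = \mathrm{PBI} \cdot \mathrm{BF}_P =
\mathrm{BF}_{BS}$ are verified to 1e-9 relative. Spearman correlation is
undefined (with reason) on zero-rank-variance input; the closed form
$1 - 6\sum d_i^2 / (n(n^2-1))$ is the test oracle on tie-free data, to
1e-12. The PDB writer enforces column capacity (B < 1000, coordinates
< 10⁴ Å) and the round trip preserves coordinates to 0.001 Å and
B-factors to 0.01 Å².

## Limitations

* PDB fixed-column input only; mmCIF is not parsed (convert upstream).
* No per-residue B-factor normalization, occupancy weighting,
  anisotropic B (ANISOU is skipped), symmetry mates or biological
  assemblies.
* The indices presuppose meaningful crystallographic B-factors; models
  refined with uniform or dummy B yield uninformative values that the
  quality warnings only partially catch.
* Accession-based checks require network access, and full-benchmark
  reproductions require a local copy of the corresponding distribution;
  both are exercised by the suite only where those resources exist.
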