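---
title: "Methods: A-tract periodicity, intrinsic bends, and NAP comparative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-tract periodicity, intrinsic bends, and NAP comparative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvenap)
```

# The scientific problem

Bacterial chromosomes carry a characteristic periodic signal: short runs of
adenines or thymines (A-tracts) recur in phase with the DNA helical period of
roughly 10.5 bp. Phased A-tracts bend the helical axis in a consistent
direction, so this periodicity is the sequence signature of *intrinsic DNA
curvature* — bending encoded in the sequence itself, independent of bound
proteins. Intrinsic bends have been proposed to collaborate with
nucleoid-associated proteins (NAPs), particularly DNA-bridging NAPs such as
H-NS, StpA, MukB, Lrp and Fis, in compacting the nucleoid into plectonemic
loops, and stronger curvature has been linked to resistance against foreign
DNA integration, connecting it to anti-phage defences such as CRISPR.

`curvenap` implements the full analysis chain used to probe these
relationships comparatively:

1. **Periodicity index (MaxQ\*)** — a genome-wide scalar measuring how
   strongly A-tract spacings cluster at the helical period.
2. **Intrinsic bend prediction** — an A-tract wedge model locating individual
   curved loci.
3. **PSSM binding-site scanning** — NAP binding potential from
   position-specific score matrices with background-calibrated cutoffs.
4. **Windowed correlation** — do predicted bends and predicted binding sites
   co-occur along a chromosome?
5. **Group statistics** — Mann-Whitney U comparisons of MaxQ\* across genomes
   grouped by NAP or CRISPR presence, and Fisher exact tests of NAP-CRISPR
   co-occurrence.
6. **Synthetic data** — generators for every input so the whole pipeline is
   testable without downloads.

# The MaxQ\* periodicity index

## Model

A-tracts are operationalized two ways: the dinucleotides AA/TT (`A2T2`) and
the tetranucleotides AAAA/AAAT/AATT/ATTT/TTTT (`AT4`). Both word sets are
closed under reverse complement, so scanning one strand suffices. For tract
start positions $p_1 < p_2 < \dots$, the spacing histogram counts

$$N(s) = \#\{(i,j): i<j,\ p_j - p_i = s\}, \qquad 1 \le s \le s_{\max}.$$

$N(s)$ mixes the curvature signal with a strong 3-bp periodicity from
protein-coding frames, broad non-stationarity, and spikes from repeats. The
filtering pipeline, in order:

1. **Coding-signal smoothing**: centered moving average of width 3. A 3-point
   average annihilates any period-3 component exactly.
2. **Detrending**: a centered moving average of width 21 estimates the local
   trend (21 = two helical turns, so the 10.5 bp oscillation itself
   contributes nothing to the trend); the relative deviation is
   $d(s) = \bar N(s)/\mathrm{trend}(s) - 1$ where the trend is positive, and
   0 elsewhere. Working with the *ratio* makes the spectrum invariant to
   rescaling all counts — genome length and tract density cancel.
3. **Winsorization**: $|d|$ is clipped at $5 \times 1.4826\,\mathrm{MAD}(d)$,
   damping spikes from tandem repeats without touching a genuine sinusoidal
   signal (a sinusoid's extremes sit near 2 robust SDs). If the MAD is zero
   the step is skipped.

Moving averages are evaluated on the full $s = 1..s_{\max}$ range with
symmetric window shrinkage at the edges, and the signal is then restricted to
$s_{\min}..s_{\max}$, so the reported left edge always sees full windows.

The spectrum is a direct Fourier transform on an explicit period grid,

$$P(T) = \frac{1}{n}\Big|\sum_s d(s)\, e^{-2\pi i s/T}\Big|^2,$$

scaled by the mean of $P$ over the out-of-band periods (2–9 and 12–20 bp) so
that the background level of the scaled power $Q(T)$ is 1 by construction.
`maxq` is the grid-wide maximum of $Q$; `maxq_star` restricts the search to
9.5–11.5 bp, the band where curvature-related periodicity lives — peaks
outside it (for instance the 9 bp signal of collagen-like repeats) are
excluded by design.

## Parameter choices

| Parameter | Default | Why |
|---|---|---|
| `s_min`, `s_max` | 5, 154 bp | ~15 helical turns; period resolution $\Delta T \approx T^2/\text{range}$ needs a range ≥ ~110 bp to separate 9.5 from 11.5 bp |
| `smooth_window` | 3 | exact null of the 3-bp coding signal |
| `trend_window` | 21 | two helical turns: the band signal is invisible to the trend |
| `winsor_z` | 5 | clips repeat spikes, passes sinusoids |
| period grid | 2–20 bp, step 0.02 | dense sampling makes the band maximum exact on the grid |
| band | 9.5–11.5 bp | curvature-related periods |

The original periodicity software's filtering constants are not published;
this pipeline is a declared re-derivation, not a bit-compatible clone.
Absolute MaxQ\* values are therefore comparable **across sequences scored by
this package** but are not expected to match previously published means
numerically. Every published comparison this package reproduces is
relative or property-based for exactly this reason.

# Intrinsic bend prediction

Each maximal run of A (or of T) of length ≥ 3 contributes a planar wedge
vector: magnitude from a run-length table (3 bp → 9°, ≥ 4 bp → 18°,
saturating — long runs are rigid but not progressively more bent), direction
the run center's helical phase $2\pi (c \bmod 10.5)/10.5$. The net deflection
of a segment is the magnitude of the vector sum: runs spaced whole turns
apart add collinearly, antiphase runs cancel. Two detector presets are
shipped: `60w100` (≥ 60° within ≤ 100 bp) and `45w60` (≥ 45° within ≤ 60 bp).

Candidate segments are run-delimited windows whose *interval* (first run
start to last run end) fits the span limit; "deviates by at least X degrees"
is read as net end-to-end deflection, not path-integrated curvature. Because
one curved locus generates many overlapping qualifying windows, the reported
bends are a non-overlapping subset chosen greedily by descending deflection
(ties to the left). Without that rule, window-level bend counts would count
a single locus many times.

The wedge magnitudes and minimum run length used by the original in-house
implementation are unpublished; the defaults here are consistent with
A-tract bending magnitudes in the curvature literature (~9–18° per phased
tract) and every geometric constant is surfaced in `bend_params()`.

# PSSM scanning and cutoff calibration

`build_pssm()` is the standard log-odds model: column frequencies
$(\text{count} + 0.5)/(n + 2)$, scores $\log_2(f/\text{background})$ in bits,
background defaulting to the scanned genome's mononucleotide composition.
`score_distribution()` computes the exact null distribution of the window
score under an i.i.d. background by column-wise convolution on a 0.01-bit
lattice, and `calibrate_cutoff()` inverts its tail: the default cutoff is the
smallest score whose background tail mass is ≤ $10^{-4}$ per bp per strand
(about one expected background hit per 10 kb window per strand). The
published two-cutoff design is reproduced as this default plus a `+3` bits
stricter setting. Hits on both strands are reported, overlapping and
palindromic duplicates included — downstream window counts consume raw hits.

# Windowed correlation

The chromosome is tiled with non-overlapping 10 kb windows (trailing partial
window dropped — a single short window would otherwise be a guaranteed
low-count outlier; the policy is configurable). A feature inside one window
counts 1 there; a feature spanning a boundary contributes ½ to each of the
two windows holding its ends. Counts are raw: no composition, codon-bias or
gene-content correction of any kind. Per NAP, the site-count profile is
correlated with the bend-count profile by the product-moment coefficient,
with the two-sided p-value from the $t$ transform on $n-2$ degrees of
freedom.

# Group statistics

* **Mann-Whitney U**: midrank ties; for total $n \le 16$ the two-sided
  p-value is exact (2 × the smaller tail of the enumerated rank-split
  distribution, capped at 1); above that, the normal approximation with
  tie-corrected variance and a 0.5 continuity correction. Exhaustive
  enumeration shows the two branches differ by at most 0.0109 in p at 8+8,
  so the crossover is safe at the resolutions reported anywhere in this
  package.
* **Fisher exact**: two-sided p as the sum of hypergeometric probabilities
  not exceeding the observed table's (relative tolerance $10^{-7}$, the same
  convention as `stats::fisher.test`). This convention was chosen because it
  reproduces the published golden p-values including the zero-cell table
  (7, 268, 0, 167) → 0.048, where one-sided, doubled and mid-p conventions
  visibly disagree. Odds ratio $(n_1 n_4)/(n_2 n_3)$, with ∞ allowed.
* **No multiple-testing correction** anywhere, matching how the published
  per-NAP tables report raw p-values.
* The NAP-controlled CRISPR comparison restricts to genomes possessing the
  NAP and re-runs the group comparison on the CRISPR flag.

A caveat surfaced by testing: in the published NAP × CRISPR contingency
table, the printed cell counts imply an odds ratio *below* 1 for the three
rows flagged as positively associated (the printed p-values do reproduce
from those cells, so the cells are the real data). The package defines the
positive-trend marker honestly as OR > 1 with p < 0.01; on those printed
rows it therefore reports a negative direction.

# What the synthetic world does and does not establish

The generators state a world deliberately simpler than a real chromosome:

* `random_genome()` — i.i.d. bases at a set GC fraction. Real genomes have
  codon structure, strand bias and repeats; none are emulated.
* `plant_periodic_arrays()` — arrays of 5-bp A- or T-runs with start-to-start
  spacings alternating 10/11 bp (averaging the 10.5 bp period on the integer
  lattice, which is also how phased tracts occur in real sequence). Spacers
  between tracts are C/G so planted runs never merge. Defaults (300 arrays
  of 8 tracts on 500 kb) make the planted signal unambiguous.
* `plant_motif_sites()` — sites sampled column-wise from the motif's
  frequency matrix, a chosen fraction placed within a proximity window of
  ground-truth anchors. The site-near-bend dependence is geometric, not
  mechanistic.
* `make_fixture_sites()` — a random consensus with per-position mutation
  probability (1 − sharpness). Fixture width defaults to 16 bp, the scale of
  curated NAP site collections (IHF ~13 bp, H-NS/Fis ~15–16 bp); at
  substantially smaller widths the motif carries too little information for
  a $10^{-4}$-calibrated cutoff to recover 90% of sites sampled from the
  smoothed frequencies — a property of the stated world, not of the scanner.
* `simulate_attribute_table()` — per-group Normal MaxQ\* draws clipped at 0
  (the index is a non-negative peak height; at the published group means and
  SDs the clipped mass is < $10^{-4}$).

A green test therefore establishes that the algorithms recover signals they
are pointed at and stay calibrated under a null — not that any biological
conclusion holds. The headline published results (the 573-genome group
means, the E. coli window correlations of 0.55–0.62, the CRISPR U-test
p = 0.009) require the original genome collection, curated site collections
and CRISPR annotations, and are intentionally outside the desk-scale test
surface; what is reproduced exactly are the published contingency-table
p-values, which depend only on printed counts.

All generators consume R's default Mersenne-Twister stream seeded
explicitly, so every synthetic object is a pure function of its parameters
and seed.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in all BED output; the
  boundary case [9999, 10000) against a 10 kb window edge belongs wholly to
  window 0.
* N never matches a tract word, breaks A/T runs, and voids PSSM windows; no
  imputation. Soft-masked (lowercase) input is uppercased and treated as
  plain sequence. Other IUPAC ambiguity codes are mapped to N with a
  warning.
* Chromosomes are treated as linear; tract pairs spanning the origin of a
  circular chromosome are ignored (at most $s_{\max} = 154$ bp of a
  multi-megabase molecule).
* All-zero histograms, empty run lists and empty hit lists propagate to
  defined zero results; a zero background spectrum yields MaxQ\* = 0 rather
  than 0/0.
* Constant count vectors make a correlation undefined: the functions error
  (or return an error marker in batch paths) instead of emitting a number.
* Greedy bend selection breaks exact deflection ties by leftmost start, so
  results are deterministic.

# Known limitations

* MaxQ\* values are on this package's own scale (see above).
* The wedge model is planar; full 3-D axis-trajectory integration (roll,
  tilt, twist per dinucleotide) is out of scope.
* Windowed correlations come with no autocorrelation correction, mirroring
  the published analysis; spatial dependence between adjacent windows makes
  the p-values optimistic in absolute terms.
* Species-level deduplication, orthology lookups and database retrievals are
  input-curation steps outside the package: presence/absence arrives as an
  attribute table.
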