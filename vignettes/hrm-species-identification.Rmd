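---
title: "Identifying fish species from melt curves: the models behind meltmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fish species from melt curves: the models behind meltmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltmark)
```

## The problem

Commercially valuable sea breams (Sparidae) — red porgy, common dentex and
their lookalikes — are routinely sold filleted, frozen or cooked, in which
state morphological identification fails and substitution with cheaper
congeners becomes profitable. DNA-based surveillance works because short
mitochondrial fragments (*COI*, *cytb*, *16s*) carry fixed differences
between these taxa and between geographic stocks, while staying nearly
invariant within them. meltmark implements the in silico side of such a
surveillance workflow end to end: choosing a short diagnostic marker from a
multi-species alignment, predicting how PCR, restriction digestion and
high-resolution melting (HRM) behave on it, and classifying unknown samples
from their melt curves.

## In silico PCR

Primer binding is modeled as ungapped IUPAC-aware matching: a primer base
pairs a template base when the template base lies in the primer base's
degeneracy set (so `R` covers A and G; an ambiguous *template* position
counts as a mismatch unless the primer base covers the whole set). A site
is accepted with at most `maxMismatches` incompatibilities (default 2,
because literature-sourced universal primers must bind templates they were
not designed on) and none in the 3'-terminal `clampLen` bases (default 3):
polymerase extension is far more sensitive to 3' mispairing than to
internal bulges. Product length follows the gel convention — forward 5' end
through reverse 5' end inclusive, so the printed size of an assay is the
full amplicon including both primer footprints. Circular templates
(complete mitogenomes) are scanned across the origin by doubling.
Coordinates are 0-based half-open internally and 1-based inclusive in every
user-facing table. All overlapping and nested products are reported; no
polymerase-competition model is attempted, so the drop-out of long
multiplex bands in degraded tissue is outside what these predictions can
show.

## Duplex thermodynamics and the Tm convention

Primer melting temperatures use the unified nearest-neighbor parameter set
(ten stack terms plus initiation terms with the terminal A·T penalty,
stored as a versioned data file in `inst/extdata/nn_unified.tsv`, not in
code), entropy salt correction $0.368\,(N-1)\ln[\mathrm{Na^+}]$, and

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15 .$$

Published primer tables rarely state which formula produced their Tm
column, so the two free knobs — monovalent salt and total strand
concentration — are fitted once by a deterministic grid search
(`calibrateTmConvention()`: Na⁺ 30–300 mM × $C_T$ $10^{-7.6}$–$10^{-5.4}$ M)
minimizing the mean absolute error over the 22 reported primer Tms shipped
with the package. The search lands at Na⁺ = 100 mM, $C_T = 10^{-6.2}$ M
(MAE 0.97 °C, worst single error 2.24 °C), and those values are frozen as
the package defaults. Degenerate primers average ΔH and ΔS over their
concrete expansions (capped at 64), mirroring how design tools treat an
oligo pool.

Amplicon melting uses the unimolecular long-duplex approximation: melting
temperature $T_m = \Delta H/\Delta S$ with salt-corrected entropy and no
concentration term, and a two-state helicity

$$\theta(T) = \frac{1}{1 + \exp\!\big[\tfrac{\Delta H_{melt}}{R}
  (\tfrac{1}{T_m} - \tfrac{1}{T})\big]},$$

scaled to 100 %. On HRM timescales long products re-anneal
intramolecularly, and what the classifier consumes is curve shape and
*relative* Tm, which this approximation preserves. A windowed variant
(default 50 bp windows stepped by 10) averages per-window helicities to
produce the compound transitions of multi-domain amplicons; with the
window equal to the amplicon it reduces exactly to two-state. No
partition-function (Poland–Scheraga) melting and no heteroduplex model:
mtDNA is effectively haploid here, so saturating-dye homoduplex curves are
the observable.

## RFLP prediction

Restriction enzymes are defined by a concrete recognition site and a cut
offset; the three built-ins (HindIII `A^AGCTT`, Sau3AI `^GATC`, XbaI
`T^CTAGA`) are palindromic, so top-strand scanning finds every site, and
non-palindromic definitions are rejected at construction rather than
silently half-scanned. Fragments always sum to the input length; a
site-less amplicon yields one full-length fragment, which is itself
diagnostic. Band matching against gel estimates is greedy one-to-one
pairing within a relative tolerance (default 12 %, the read-off error
implied by sizing ~700 bp products against a 100 bp ladder), and the score
is matched pairs over the larger pattern; `rflpKey()` applies this
pairwise across groups and flags pairs whose patterns are identical at
tolerance — the situation where an assay cannot exclude a lookalike taxon.
Fragments under 40 bp are kept but flagged as possibly unresolvable.
Methylation sensitivity and partial digestion are out of scope.

## HRM normalization and two-stage clustering

Raw melt curves are normalized between straight baselines fitted by least
squares inside a pre-melt and a post-melt temperature window (defaults
65–68 °C and 92–95 °C on the 65–95 °C, 0.2 °C acquisition grid), giving
percent-helicity curves pinned at 100 %/0 %; the per-sample Tm estimate is
the interpolated 50 % downward crossing. Baselines whose fitted upper and
lower lines touch anywhere in the analyzed range are rejected as
degenerate rather than silently dividing by near-zero.

The commercial analysis software behind HRM genotyping documents exactly
two stringency knobs but not its algorithm; meltmark's clustering is an
explicit reconstruction built from those two knobs, stated as such:

1. **Tm difference threshold** (default 0.2 °C): single-linkage grouping
   on the 1-D Tm estimates, split wherever the sorted gap reaches the
   threshold — samples at least that far apart never co-cluster.
2. **Shape sensitivity** (default 75 %): within each Tm group,
   average-linkage hierarchical clustering on the RMS distance between
   normalized curves, cut at $d_{cut} = (1 - s/100)\,d_{scale}$ where
   $d_{scale}$ is the largest pairwise curve distance in the dataset. The
   linear mapping from the percent knob to the cut height is the
   package's committed interpretation of the vendor's dial.

Per-sample confidence in cluster $c$ is the softmax
$100 \exp(-d_{ic}^2/2\sigma^2)/\sum_{c'} \exp(-d_{ic'}^2/2\sigma^2)$ with
$d_{ic}$ the RMS distance to the cluster mean and $\sigma$ the pooled
within-cluster RMS deviation floored at $10^{-3}$; confidences sum to 100
per sample. Confidence is defined per sample (published reports quote
ranges over samples, which is consistent with either reading). Everything
is deterministic — hierarchical methods only, cluster ids ordered by
cluster mean Tm, ties broken on sorted sample id — so memberships are
invariant to input order and repeated runs are byte-identical. Curves that
never cross 50 % are excluded from stage 1, clustered by shape only and
flagged. Temperature-shift superimposition exists as a config flag but is
off by default. Exact numerical reproduction of vendor confidence values
(97–98.5 % and the like) is explicitly not attempted; the property-level
behavior — correct partitioning, high confidence for clean references,
novel haplotypes separating — is what the test suite pins down.

An unknown is assigned by re-clustering it with the reference set: it
inherits the majority label of its cluster when its confidence reaches the
floor (default 95 %), and otherwise returns
`"unassigned — possible new variant"` with the nearest labeled cluster —
the wanted behavior for novel haplotypes, which should trigger sequencing
rather than a confident wrong call.

## Marker-window discovery

`scanDiagnosticWindows()` enumerates every alignment window of 100–160
columns (the degraded-sample-safe size range; the default upper bound is
160 rather than 150 because a deployed 156 bp fragment must qualify) such
that (a) each group is column-identical inside the window, (b) at least
one interior column separates every must-discriminate group pair, and (c)
both 18-column flanks have at most 2 columns variable across *all*
sequences, so near-universal primers can be read off the flank consensus
with IUPAC codes at the variable spots (more than 3 degenerate positions
rejects the candidate). Windows with gap columns are allowed and flagged —
a one-base indel between groups is itself informative. Candidates are
ranked by diagnostic-column count, ties to the shorter window. Amplicon
lengths are reported per group after gap removal, since an indel makes
them differ. An independent brute-force enumerator re-checks the scan in
the test suite. `predictAssaySeparation()` then reports per-pair percent
identity (gap columns count as differences) and the simulated |ΔTm| and
curve distance of the group consensus amplicons, flagging pairs the melt
assay can separate. Hairpin/self-dimer screening and multiplex
optimization are not modeled.

## What the synthetic generator emulates — and what it does not

`simulateReferencePanel()` produces the study conditions every stochastic
test runs under: 6 groups × 3 members of a 600 bp fragment, inter-group
divergence 0.04 substitutions/site and intra-group 0.005 (matching the
~81–99 % pairwise identity range typical of congeneric Sparidae on these
fragments), and one planted 113 bp marker window with fully conserved
18 bp flanks. The marker interior carries a ladder of diagnostic
substitutions — group $g$ converts $2(g-1)$ planted A positions to G — so
every group pair differs inside the window and the group amplicons form a
Tm ladder with ~0.7–1 °C rungs. The marker region is drawn AT-rich (60 %
A/T, as in fish mtDNA), which keeps the hottest rung's transition
comfortably inside the 65–95 °C acquisition window. Substitution noise is
uniform over the twelve base changes and never lands inside the marker
window, mirroring a marker chosen precisely for within-group invariance.
`simulateMeltCurveSet()` adds the acquisition artifacts normalization must
remove: triplicate wells, i.i.d. Gaussian fluorescence noise (sd 0.3
percent-scale units), and a random linear baseline (slope −0.15 to −0.05
per °C, intercept 8–15). `simulateMarketSurvey()` draws declared-vs-true
labels with a seeded mislabeling rate as ground truth for the pipeline.

All randomness flows through one seed; identical seeds give bit-identical
FASTA output. This is deliberately *not* a phylogenetic simulator: no tree
structure, no rate heterogeneity, no transition bias by default, no
heteroplasmy, and the melt curves inherit the two-state model's idealized
symmetric transitions. Passing tests therefore demonstrate that the
algorithms recover planted structure under realistic noise and divergence
levels — not that wet-lab curves, with their instrument drift, plate
effects and chemistry-dependent transition widths, will cluster equally
cleanly.

## Numerical and design choices

- Case-insensitive sequence input, uppercase canonical, `U` read as `T`;
  the only gap character is `-` (`.` is rejected) so one alignment dialect
  is in force; FASTA ids are taken up to the first whitespace.
- Blank cells in the sample-panel table read as 0 for counts and empty
  text for regions, column-for-column as such tables print; the literal
  region code `NA` (North Aegean) survives loading.
- Degenerate-baseline detection uses a scale-relative epsilon
  ($10^{-6}\times$ the curve's magnitude) so float noise cannot sneak a
  flat curve past the check.
- The softmax floor $\sigma \ge 10^{-3}$ keeps confidences defined when a
  cluster is internally identical (noiseless references).
- Problem sizes in the test suite — 100 seeded plate replicates for
  cluster recovery and novel-variant behavior, 50 seeded alignments
  compared column-by-column against the brute-force validator, 1000
  random digests for length conservation — were chosen as the smallest
  sets that exercise every stochastic regime the generator produces.

## Known limitations

Mismatch-counted binding ignores binding thermodynamics, so a 3'-clamped
site with two destabilizing internal mismatches is treated like a perfect
one; the two-state melt model understates transition width and cannot
produce the multi-domain shoulders of long amplicons unless the windowed
model is chosen; the clustering reconstruction matches the vendor
software's documented behavior, not its implementation; and a novel
haplotype whose Tm happens to coincide with a *different* reference
taxon's cluster is indistinguishable from that taxon by melt alone — as
in the laboratory protocol, such calls are resolved by sequencing.
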