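---
title: "Methods: conversion-aware site calling and footprint meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conversion-aware site calling and footprint meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larpmap)
```

## The problem

PAR-CLIP maps where an RNA-binding protein touches RNA: cells incorporate
4-thiouracil, UV crosslinking covalently traps protein–RNA contacts, and the
crosslinked uridine is read out after reverse transcription as a T-to-C
conversion in the aligned reads. For the yeast La-related proteins (Slf1,
Sro9), which travel with translating ribosomes, the analytical questions are
positional: where inside a transcript are the crosslink sites (5'UTR, ORF,
3'UTR; early or late in the ORF), how do they relate to ribosome footprints
of different classes (standard 28–30 nt, short 20–22 nt, disome 57–63 nt),
what sequence and structure context do they sit in, and how do reporter
assays quantify the downstream consequences (stop-codon readthrough,
programmed frameshifting, mRNA distribution across polysome fractions).

`larpmap` implements that analysis chain as a set of composable stages, and
pairs it with a seeded simulator that plants crosslink sites with known
positions, motif frames and footprint offsets, so every stage can be
validated against ground truth.

## Site calling

The caller works per *read group*: a maximal set of reads on the same
transcript and strand whose intervals overlap transitively. Groups with
fewer than 5 reads are discarded, as are reads shorter than 13 nt.

Within a group two event sets are collected:

* **signal** — conversion positions (one event per conversion per read);
* **background** — covered, conversion-capable positions without a
  conversion (reference T on the plus strand, A on the minus strand; one
  event per read per position). When no sequence is supplied every covered
  position is treated as capable.

Each set is summarized by a count-normalized Gaussian kernel density
(bandwidth 3 nt): \(s(x) = \frac{1}{|E|}\sum_{e \in E} \phi_3(x - e)\).
Normalizing each density to its event count is essential: the background
set is roughly the read length times larger than the signal set, so raw
kernel sums would never let signal exceed background at realistic
conversion rates. The normalized densities compare the *shape* of the
conversion distribution against the shape of the opportunity distribution,
which is the contrast the method intends.

Positions covered by fewer than 5 reads are masked. Maximal runs of
unmasked positions with \(s(x) > b(x)\) are *interaction regions*. Each
region is extended to the contiguous block of positions with depth ≥ 5
around it — the read-supported cluster — and regions falling in the same
block merge. This extension reflects how the upstream tool reports
clusters: the 11–100 nt width window and the rejection of clusters larger
than 100 bp ("large spans of overlapping binding sites") both refer to
read-supported extents, and a single-nucleotide crosslink would otherwise
produce interaction runs of ~9–11 nt that the lower width bound would
reject almost at random.

A cluster is accepted when it carries at least 2 conversions contributed by
at least 2 distinct reads and its width is 11–100 nt. Its **mode location**
is the position maximizing \(s/(s+b)\), ties broken leftmost. When the
sequence is known the argmax is restricted to conversion-capable positions:
the ratio is a conversion likelihood and is only meaningful where a
conversion could occur; without the restriction the argmax drifts into
background troughs between T positions (in simulations the within-±2 nt
mode accuracy drops from ~99% to ~80%).

Parameters (all exposed through `site_params()`):

| parameter | default | unit | role |
|---|---|---|---|
| `bandwidth` | 3 | nt | Gaussian kernel SD for both densities |
| `min_read_len` | 13 | nt | read length filter |
| `min_group_reads` | 5 | reads | overlapping group minimum |
| `min_depth` | 5 | reads | depth needed for a defined estimate |
| `min_conversions` | 2 | events | conversions per cluster |
| `min_conversion_reads` | 2 | reads | distinct converted reads per cluster |
| `min_width`, `max_width` | 11, 100 | nt | accepted cluster widths |

## Annotation and quantification

Sites are assigned to 5'UTR / ORF / 3'UTR by the region containing their
mode (the site's point summary), so a boundary-spanning site follows its
mode. Transcripts with at least one accepted site are *targets*.

Per-transcript quantification uses
\(\mathrm{rpkm} = \frac{c / N \times 10^6}{L_{kb}}\) with \(c\) the assay's
read count (for CLIP, only reads inside accepted clusters), \(N\) the assay
library total and \(L_{kb}\) the coding length in kb. CLIP enrichment is
CLIP rpkm over total-RNA rpkm; translation efficiency and disome abundance
are the footprint-class analogues. Denominators below an RNA rpkm floor of
0.1 are excluded rather than producing unstable ratios; the floor is a
package choice, exposed as an argument, made because tiny denominators
otherwise dominate ratio distributions.

The polysome:monosome statistic is deliberately a size-factor-normalized
log2 ratio with a pseudocount (default 0.5), not a negative-binomial
differential model: `log2((poly/sfP + c)/(mono/sfM + c))` with
median-of-ratios size factors. Group comparisons use a Mann–Whitney test
computed exactly (exhaustive enumeration of all group assignments,
ties included) when `nA + nB <= 12` and by the tie-corrected normal
approximation above that; the boundary is where enumeration (≤ 924
assignments) stays instant.

## Metagene profiles

Three anchorings are provided. The ORF-centile profile maps each position
to `floor(100 * (pos - orf_start)/orf_len)` and normalizes counts to sum
to 1. Start/stop-anchored profiles count positions at nt offsets from the
first nt of the start or stop codon, divided by the number of contributing
transcripts. Mode-centered footprint profiles collect per-nt read density
in ±100 nt windows around site modes; windows overhanging transcript ends
contribute only their defined offsets, and each window is normalized to its
own mean before averaging so deep sites do not dominate (global
normalization is available by flag, since the corresponding published
figures do not state their normalization).

Read-to-position assignment defaults to full-span coverage. For locating a
planted peak, coverage of long centered reads is a plateau — every position
within half a read length of all centers has identical depth — so the
argmax of a coverage profile is an arbitrary plateau edge. Peak-position
checks therefore use midpoint assignment (`assign = "center"`), which
concentrates each read at one position and makes the aggregate argmax a
meaningful estimator of the planted offset; 5'-end assignment is available
for periodicity work.

## Motif framing and structure windows

The YGSU consensus (Y = C/T, S = G/C, U = T on the DNA alphabet) is scanned
as a fixed degenerate pattern (any IUPAC pattern is accepted); de novo
discovery is out of scope. A hit's frame is
`(g_position - orf_start) mod 3`. Two tallies exist: per-hit (every match
counts) and per-site (each site votes through the hit nearest its mode).
The headline "fraction of sites with the G in frame X" statistic is
per-site, matching how the corresponding result is stated for binding
sites; with read-extent clusters of ~40–60 nt, per-hit tallies are diluted
by chance matches (about one spurious YGSU per 64 nt scanned), which is a
property of the wide cluster interval rather than of the framing signal.

Structure context uses per-nucleotide PARS-like scores: `pars30` sums a
30-nt window (one ribosome footprint), and `pars30_around_mode` evaluates
the tiling half-open windows [−45,−15), [−15,+15), [+15,+45) around the
mode. Windows leaving the defined track are flagged `NA` and excluded from
aggregates.

## Reporter arithmetic

Dual-luciferase percentages are computed per replicate —
`100 * (Fluc/Rluc)_test / (Fluc/Rluc)_control` with CAA as control for
stop-codon readthrough and the frame-0 reporter for ±1 frameshifting — then
summarized as mean ± sem. Normalizing per replicate before averaging (the
alternative would pool the control first) keeps replicate variance honest;
pooled normalization is available by flag. qPCR amounts use the
efficiency-corrected form \(E_t^{-Cq_t} / E_s^{-Cq_s}\) against a spiked-in
control, with amplification factors from the dilution-series slope
(`10^(-1/slope)`). Percentages per gradient fraction are computed per
replicate and summarized the same way. The two-way ANOVA + Tukey wrapper
delegates to `stats::aov`/`TukeyHSD`.

## What the simulator does and does not emulate

The generator (defaults in `sim_config()`) builds 20 plus-strand
transcripts with 30–80 nt 5'UTRs, 300–900 nt ORFs (ATG, sense codons, one
stop) and 50–150 nt 3'UTRs. One crosslink site per transcript is placed in
the ORF with density ∝ \(x^3\) of relative ORF position (mean relative
position 4/5, reproducing the observed 3'-ORF bias; the exponent is the
generator's definition of that regime). A YGSU instance is written at the
site with its G in frame 0 and the crosslink on its U. CLIP reads
(Poisson(50) per site, 13–40 nt, uniform lengths) each cover the crosslink
and convert there with probability 0.5; background reads (10% of expected
site reads) are uniform and never convert. Footprint classes draw lengths
from their exact ranges with centers at the crosslink plus a class offset
(0 for standard/short, +30 nt for disome — roughly one ribosome downstream)
and Gaussian jitter (SD 2 nt). RNA-seq counts are negative binomial
(dispersion 0.1); structure tracks are baseline 0.2 + N(0, 0.5) noise with
+1 inside ±15 nt of each site.

Deliberately not simulated: rRNA contamination, multimapping, PCR
duplicates, 4TU labeling chemistry, multiple crosslink positions per site,
strand-minus biology (minus-strand handling is exercised at the IO layer),
and any correlation structure between assays beyond shared site positions.
Passing tests on these data therefore demonstrate the correctness of the
computations and the recoverability of planted effects under idealized
noise — not performance on real libraries, where crosslink multiplicity,
non-uniform coverage and contamination will widen clusters and blur modes.

## Numerical and validation choices

* Coordinates are 0-based half-open throughout; argmax ties break leftmost.
* Each simulator stage reseeds from `seed` plus a fixed stage offset, so
  any stage is reproducible in isolation and a fixed configuration is
  byte-identical end to end (`run_pipeline` writes md5 checksums into its
  provenance JSON).
* Validation problem sizes: the caller is checked against a naive
  brute-force implementation (loops, exhaustive scans) on 200 random
  instances of up to 50 reads; recovery is measured on 10 replicate runs of
  20 planted sites; positional-bias and framing checks use 100 transcripts
  x 20 sites and 40 transcripts respectively; rank tests are enumerated for
  all group sizes with nA+nB ≤ 10. These sizes make the full suite run in
  well under a minute while keeping Monte-Carlo margins comfortable.

## Known limitations

* Clusters are reported at read-supported extent, so reported widths track
  read length and depth more than crosslink geometry; the mode is the
  precise coordinate.
* The polysome:monosome ratio is a normalized log-ratio without shrinkage
  or inferential output.
* `quintile_distribution` and covariate columns treat external scores as
  opaque inputs; no attempt is made to recompute them.
* The simulator's uniform read-placement model makes recovery easier than
  real libraries with positional bias within sites.
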