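---
title: "Quantifying TF-nucleosome binding on a tiled oligo library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TF-nucleosome binding on a tiled oligo library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pioneerseq)
```

## The assay this package models

Most transcription factors (TFs) bind naked DNA far better than DNA wrapped
around a histone octamer, yet many regulatory elements sit inside
nucleosomes. A small class of pioneer factors can engage nucleosomal DNA
directly. A competitive way to measure this is to build a pooled library of
nucleosomes in which a TF binding site (TFBS) has been placed at every
possible position along well-characterized nucleosome positioning sequences
(NPSs) such as Widom 601, 5S rDNA and the MMTV LTR, incubate the entire
pool with a purified TF, separate TF-bound from unbound nucleosomes by
electrophoretic mobility shift (EMSA), and sequence the DNA in each gel
band. Sequencing read counts then report, for each library member, how
strongly the TF engaged a nucleosome with its site at that particular
translational and rotational setting. The same pool, digested with
micrococcal nuclease (MNase) and sequenced, reports where the histone
octamer actually sits on each sequence.

`pioneerseq` implements the full computational side of this design:

1. **design** — scrub the NPS backbones of pre-existing motif matches, tile
   a TFBS by substitution at every grid offset, flank with primers to 230-nt
   oligos, select *in vivo*-targeted nucleosome (ITN) windows, and emit a
   validated manifest + FASTA;
2. **reads** — turn paired-end band FASTQ into per-sequence counts
   (quality trim, merge, primer trim, length filter, identity-threshold
   mapping);
3. **supershift** — the relative-supershift log2 statistic against
   nonspecific controls, positional profiles with replicate SEM,
   concentration selection, and ITN-level analyses;
4. **mnase** — per-base protection, fragment-center histograms, population
   summaries, protection centers, formation efficiency;
5. **simulate** — a fully seeded generator of demo libraries, EMSA band
   read pools and MNase fragment pools with ground truth, so that every
   stage above is testable end to end without any external data.

## Coordinates and library geometry

Inserts are 191 nt, 1-based, with a 147-bp core at `[23, 169]` and the dyad
(the nucleosome's central base pair) at position 96. A tiled entry records
its `dyad_offset`: the motif-center position minus 96, negative to the
left. For even-length motifs the "center" is the left-of-center base, so
offsets are reproducible. The default tiling grid is offsets −74…+74 — 149
positions covering the whole core plus one position in each 22-bp linker;
the grid is an interpretation (the count and the presence of linker
positions are fixed by the design, the exact span is configurable in
`tile_tfbs()`). Placement is always substitution into the fixed-length
insert, never insertion, so dyad coordinates stay comparable across
offsets. Primers default to 19 + 20 nt so that 19 + 191 + 20 = 230.

Motif scrubbing removes pre-existing matches from a backbone with one
substitution per hit per round: at the position with the largest score
contribution (leftmost for consensus motifs, whose contributions are
uniform), replaced by the contribution-minimizing base, alphabetical on
ties, complemented back for minus-strand hits; rescanning iterates to a
fixed point (cap 10 rounds, then a hard error listing residual hits).
Scrubbing is idempotent and edits are confined to hit windows.

ITN windows are 191-nt sequences centered on a called nucleosome; a
candidate is retained only if it contains an identifiable TFBS and its
nucleosome-formation score is ≥ 0.7 (strictly lower scores are removed).
The published genomic scoring function is out of scope here; the package
ships a pluggable scorer interface whose default, `periodicity_score()`,
maps the 10-bp AA/TT/TA periodicity (vector strength, doubled and capped
at 1) into [0, 1]. It ranks strongly periodic sequences above random ones
but is **not** equivalent to trained nucleosome-occupancy models; supply
your own scorer, or precomputed scores, for real designs.

## The read pipeline

Stages run in a fixed order — quality-trim → merge → primer-trim →
length-filter → map — with the thresholds of the assay's standard
processing chain: 3′ quality trimming at q30 by the partial-sum rule (cut
where the running sum of `q − 30` from the 3′ end is most negative),
merging only with ≥ 20 overlapping bases and ≤ 2 mismatches (best overlap
= max of matches − mismatches over all offsets; consensus takes the
higher-quality base, the forward base on ties), anchored primer removal
with ≤ 2 mismatches per end, an inclusive 174–220-nt length window, and
mapping that demands ≥ 150 alignment columns and ≥ 98.5% identity with the
single best-identity reference (`--top_hits_only` semantics; an exact tie
across two references discards the read as ambiguous, a conservative
choice for a counting assay).

Mapping identity is matches / alignment columns under a semi-global
alignment: the read end-to-end, free end gaps on the reference. The linear
gap penalty is deliberately strong (−10 against +1/−1) because merged reads
are substitution-dominated; with a mild penalty, an indel pair can re-align
a substitution that sits next to a repeated base and nudge identity across
the 0.985 cutoff, making the stated 2-vs-3-substitution boundary (189/191 =
0.9895 accepted, 188/191 = 0.9843 rejected over a full insert) fuzzy. A
cheap ungapped screen shortlists references; the decision is always the
alignment. Every input pair ends in exactly one bucket — a count or a
named discard reason — and the table is independent of read order.

## The relative-supershift statistic

For library sequence $N$ with pseudocount $c$ and nonspecific control set
$NS$:

$$\mathrm{RS}_N \;=\; \log_2\!\left(
  \frac{(SS_N + c)\,/\,\overline{(SS_{NS} + c)}}
       {(\mathrm{Null}_N + c)\,/\,\overline{(\mathrm{Null}_{NS} + c)}}
\right)$$

where $SS$ counts come from the supershifted (TF-bound) band and
$\mathrm{Null}$ from the nucleosome band of the TF-free lane of the same
gel. The double ratio cancels gel-loading, PCR, and sequencing variability
and normalizes away each sequence's nucleosome-formation efficiency.
Controls are sequences **on the same NPS backbone** whose TFBS belongs to
other factors; reverse-complement variants of the focal factor's sites are
excluded through the motif panel's `rc_of` links, and an optional linker
screen drops any candidate motif whose linker-position variants show
binding above a bootstrap null (the set can only shrink). The overbar is
the arithmetic mean over controls (a median option exists).

Choices the formula itself does not fix, and their defaults:

* **pseudocount 0.5** on every count — the statistic is undefined at zero
  counts; 0.5 perturbs a balanced four-fold fixture by < 0.02 at realistic
  depths, and the statistic is exactly scale-invariant when the pseudocount
  scales with a band's depth;
* **input floor 10** — a sequence with fewer than 10 raw reads in the
  TF-null nucleosome band formed nucleosomes too inefficiently to
  quantify; its value is withheld (`missing_low_input`), which is what
  produces the breaks in a positional trace rather than spuriously extreme
  values;
* **replicates** aggregate as mean ± SEM (sd/√n, reported for n ≥ 2), with
  a gap where every replicate was withheld;
* **bound/unbound for ITNs** defaults to mean ≥ 1.0 log2 units — an
  explicit, configurable convention reported alongside the raw values, not
  a measured constant;
* **concentration selection** scores each concentration by the separation
  of specific vs nonspecific binding at linker positions (where binding is
  most likely), standardized by the pooled SEM; ties resolve to the lower
  concentration, so a flat titration never inflates the chosen dose;
* the ITN **distance analysis** uses Spearman correlation (robust to the
  strongly non-linear distance–binding relation) between supershift and
  the distance of the TFBS center from the MNase-protection center, and
  reports the bound fraction among ITNs within 40 bp of that center; with
  zero near-center ITNs the fraction is reported as undefined with n = 0,
  never as 0%.

## MNase analytics

Protection at base $i$ is the fraction of a sequence's mapped fragments
covering $i$ (inclusive spans). Fragment centers use the mononucleosome
size window 107–150 bp (inclusive bounds) and `floor((start + end) / 2)`
for even lengths. The "center of MNase protection" is, by default, the
protection-weighted centroid with half-up rounding (a mode-based variant
is available); it is shift-equivariant. Population summaries report the
mass within ±10 bp of a reference center and the modes of the 3-bp
moving-average-smoothed histogram (within a smoothing plateau the mode is
the raw-count argmax). Formation efficiency is the median-centered log2
ratio of nucleosome-band to naked-DNA-band counts, with the bottom 5%
flagged as poor formers.

## What the simulator emulates — and what it does not

The generator draws the four gel bands as multinomials over the manifest:
input ∝ abundance $a$, naked DNA ∝ $a(1-f)$, TF-null nucleosomes ∝ $af$,
supershift ∝ $afe$, with formation probability $f$ (default 0.8) and fold
enrichment $e$ ($e=1$ is the nonspecific baseline). Reads are the oligo ±
substitution errors, split into 150-nt mates whose overlap is ≥ 70 nt for
full-length molecules. MNase fragments draw a center from a per-NPS dyad
mixture (default: one population at the dyad, sd 2) and a length from a
truncated Normal whose mean shortens by 1 bp per minute of digestion
(155 − t at t minutes, so the canonical 15-minute histogram sits near
140 bp), clipped to [80, 191] and to the insert. Everything flows from one
seed; identical configs give byte-identical FASTQ.

Two deliberate simplifications matter when interpreting green tests:

* **substitution-only errors** — no indels, no per-cycle quality decay, no
  PCR or gel-extraction bias. Correct bases carry q40 and only
  error-injected positions carry the rate-derived Phred score; a constant
  whole-read quality at the default error rate would sit below the q30
  cutoff and the trimming stage would (correctly, per its rule) delete
  every read, which no real base caller produces.
* **geometry of edge populations** — a dyad placed ~40 bp from the insert
  edge cannot carry a mononucleosome-sized fragment inside a 191-nt
  insert; fragments are clipped to the insert, which moves their apparent
  centers inward. Mixture-recovery checks for edge populations therefore
  use a shorter length model with matching histogram bounds, and the
  canonical 107–150 window is exercised with interior mixtures.

Passing tests show that the statistics recover known inputs under this
idealized model (e.g. log2 enrichment within ±0.1 at 2×10⁵ reads/band,
mixture weights within ±0.05 at 10⁴ fragments); they cannot show
robustness to error structures the generator does not produce.

## Numerical and degenerate-input policy

Positional centroids round half-up (a flat block over [1, 50] centers at
26, reproducibly). Ambiguity codes (including N) are rejected loudly
rather than silently matched. Empty histograms, zero-read bands, empty
control sets, and sub-minimum control sets after screening are hard
errors. The tie rules — leftmost scrub position, alphabetical replacement
base, longer-overlap-then-smaller-shift merging, forward base on equal
quality, ambiguous-read discard, lower concentration — are all
deterministic and stated in the function documentation.

Problem sizes in the test-suite simulations (libraries of one or two
backbones × 1–12 variants, 2×10⁴–2×10⁵ reads per band, 10⁴ fragments, 20
seeds for recovery checks) were chosen as the smallest sizes at which the
sampling error of each recovered quantity is comfortably below its
acceptance band.

## A worked example

```{r example, eval = FALSE}
library(pioneerseq)

# design-by-simulation: 1 backbone x 2 TFBS variants x 149 offsets
man <- simulate_demo_library(seed = 1, n_nps = 1, n_tfbs = 2, n_itn = 0)

# simulate an EMSA in which the canonical KLF4 site is 4-fold enriched
specific <- man$id[man$tfbs_id == "Klf4-1"]
cfg <- simulation_config(seed = 2, reads_per_band = 2e5,
                         enrichment = setNames(rep(4, length(specific)),
                                               specific))
sim <- simulate_band_counts(man, cfg)

cs <- select_controls(man, pioneer_tfbs_panel(), tf = "KLF4",
                      nps_id = "601syn")
v <- relative_supershift(sim$counts$supershift, sim$counts$nucleosome_null,
                         cs)
mean(v$value[v$library_id %in% specific])   # ~ 2.0 = log2(4)

v$replicate <- 1L
prof <- build_profile(v, man)
plot_supershift_profile(prof)
```

## Known limitations

The default ITN scorer is a surrogate, not a trained occupancy model. The
mapper does not emit SAM/BAM and is not optimized for indel-rich reads.
Demultiplexing and PCR-duplicate handling are out of scope (samples arrive
demultiplexed; the assay's protocol does not deduplicate). The synthetic
NPS backbones are seeded random stand-ins with the real sequences'
geometry, not the published 601/5S/MMTV sequences — supply real inserts as
FASTA for real designs. Real-data figures of merit (population fractions
of particular NPSs, per-TF bound percentages at ITNs) depend on real
libraries and are not reproduced by the synthetic conditions.
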