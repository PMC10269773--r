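---
title: "Methods: mapping Argonaute-associated small guide DNAs and the RecBCD-centred statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping Argonaute-associated small guide DNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prokaryotic Argonaute (pAgo) nucleases copurify with 14–19-nt small guide
DNAs (smDNAs). When a pAgo is expressed in *E. coli*, the genomic origin of
its guides is informative about the DNA-processing events that generated
them: guides pile up between replication-termination (*ter*) traps and the
nearest co-oriented Chi site, drop abruptly on the 5′ side of Chi octamers
(5′-GCTGGTGG-3′, the RecBCD stop signal), and — under the gyrase poison
ciprofloxacin (Cfx) — become enriched between gyrase cleavage sites (GCSs)
and their upstream co-oriented Chi. `smdnaseq` implements the full analysis
of such libraries (exact alignment, strand-specific coverage, ter/Chi/GCS
statistics) together with a generative simulator of the same biogenesis
model, so every statistic can be validated by recovering planted
parameters.

## Coordinates and orientation conventions

All internal coordinates are 0-based half-open; I/O converts from 1-based
inclusive (GFF, printed genome coordinates) and passes BED through
unchanged. Every oriented site stores the 0-based start of its motif window
on the plus strand. The *reference base* of a site is the 5′-most base of
the motif in the site's own orientation (`position` for `+` sites,
`position + width - 1` for `-` sites); metaplot offsets are measured from
it along the site's orientation, so positive offsets are always the 3′
side. This single convention makes every statistic exactly invariant under
reverse-complementing the genome, which the test suite checks to 1e-10.

Density always means counts of aligned-read 5′ ends. Guides are 14–19 nt
and every downstream statistic is strand-polar, so the 5′ end is the
natural attribution point; per-base full-length coverage can be recovered
from the exported alignments if needed.

## Read processing and alignment

Reads are trimmed at the leftmost exact occurrence of the 3′ adapter, and
reads shorter than 14 nt are discarded. Alignment is exact (no mismatches),
against both strands of every replicon, with circular origin junctions
handled by scanning `sequence + first (w - 1) bases`. The aligner is a
Biostrings `PDict`/`matchPDict` dictionary per read length — exact,
deterministic, and memory-bounded by the reference length.

A read matching more than one location is assigned to the
lexicographically smallest `(replicon, match start, strand)` hit. This is a
deterministic, reproducible stand-in for an unknown aligner reporting mode;
rRNA-operon and termination-region masks absorb most genuine repeats, and a
`multimappers = "discard"` switch drops such reads instead. The first-hit
rule is intentionally coordinate-convention-dependent, so the
reverse-complement symmetry check uses the discard policy, which is exactly
flip-equivariant.

Windowed coverage is reported as RPKM (reads per kilobase per million
aligned reads) in 1,000-nt windows by default, the final partial window
normalized by its true length.

## The generative model

The simulator draws read 5′ ends from a per-position, per-strand intensity

λ(p, s) = β · m_ter(p, s) · m_chi(p, s) · m_gcs(p, s),

composed multiplicatively because every downstream statistic is a ratio.
With defaults in parentheses:

* **m_ter** — on the interval from each ter trap to the nearest co-oriented
  Chi, the strand whose 3′ end points toward the trap gets `h` (10) and the
  complementary strand `h / a`, with `a` (3) the RecBCD processing
  asymmetry. The bounding Chi is planted 15–25 kb from the trap.
* **m_chi** — the co-oriented strand is reduced to `1 − δ` (δ = 0.25) at
  each Chi reference base, recovering linearly to 1 over `w` (5,000) bp on
  the 5′ side. The linear ramp is a modeling choice; the observed profiles
  recover gradually but do not constrain the functional form, so both δ and
  `w` are exposed in the configuration.
* **m_gcs** — only in +Cfx libraries, the interval from each GCS back to
  its closest upstream co-oriented Chi (on that Chi's strand, both
  directions considered, no intervening co-oriented Chi — the same
  adjacency rule the analysis uses) is multiplied by γ (2). Overlapping
  GCS intervals are boosted once (union), not stacked.
* **Plasmid** — positions on the plasmid replicon get
  `mean(chromosomal λ) · copy_number · preference` on both strands.
  Defining the rate against the *mean* chromosomal intensity (rather than
  β) makes the planted `preference` exactly the per-copy, length-corrected
  fold that `plasmid_enrichment()` estimates, independent of how strongly
  the ter peaks skew the chromosomal average. Defaults: copy number 12
  (pBAD-type vector) and preference 12, the order observed for
  cyanobacterial pAgos in *E. coli*.

The chromosome is sampled at 51% GC (the *E. coli* genome average); all
spurious Chi octamers are scrubbed by rejection before `chi_count` motifs
are planted, so the planted set is exactly the scannable set. Read lengths
follow a configurable 14–19-nt distribution peaked at 16–17 nt; the 3′
adapter is appended so the trimming path is exercised. Everything derives
from one integer seed: the same seed and configuration give byte-identical
FASTQ files, and ground truth (sites, intensity arrays, per-read source
records) is returned alongside.

What the simulator does **not** emulate: sequencing errors, PCR
duplicates, quality-score structure, RNA contamination, and genuine genomic
repeats (the random chromosome is essentially repeat-free, so multimapping
is rare). Passing recovery tests therefore validates the statistical
machinery, not robustness to those artifacts.

### Default study conditions

Recovery tests run on a 1-Mb circular chromosome with 5×10⁵ reads per
library, 40 Chi sites, 20 GCSs, two ter traps arranged like terA/terC
around a terminus at 0.5 Mb. The Chi density (one per 25 kb) is sparser
than the real chromosome's (one per ~5.5 kb) so that the ±50-kb metaplot
flanks are dominated by background rather than by neighbouring Chi ramps;
with the real density the background itself carries the drop signature and
the planted δ is no longer the clean estimand. The smaller genomes in the
unit tests (100–300 kb) scale the ter–Chi distances accordingly; all
problem sizes are stated in the tests themselves.

## The statistics

* **ter fractions** — per ter window and strand, 5′-end counts divided by
  the total reads mapped to both chromosome strands, ×100. Windows may be
  given as fixed coordinates (the published quantification windows) or
  taken from the recorded trap-to-Chi intervals; both are supported, fixed
  windows being what the numbers in the literature use.
* **strand-ratio profile** — rolling plus/minus ratio (50-kb window, 10-kb
  step; windows wrap around circular replicons so the origin/terminus show
  no edge artifacts), computed per library and divided (+Cfx over control).
  A pseudocount of 1 read per window per strand prevents division by zero
  in sparse windows and is recorded in the output attributes.
* **Chi metaplots** — per-base densities around each unmasked Chi on the
  co-oriented (F) and opposite (R) strands, orientation-flipped, averaged
  position-wise over anchors, converted to per-base RPKM and smoothed with
  a centered moving average (400 bp). The effective smoothing span is
  forced odd so smoothing commutes with coordinate reversal. Anchors whose
  window crosses a mask contribute only unmasked offsets; per-offset anchor
  counts are tracked so means stay unbiased near masks.
* **background and drop** — background is the mean smoothed F density over
  the remote flanks (35–50 kb on both sides, F strand only; a both-strand
  variant would mix the R strand's much weaker Chi response into the
  reference level). The drop statistic is `(1 − min(F / background)) × 100`
  with the minimum searched within ±2 kb of the anchor — the minimum is
  marked "at the Chi site" without a stated window in the source analyses,
  so the window is explicit and configurable here.
* **Chi–GCS classes** — a Chi is `downstream_gcs` when a GCS lies on its 3′
  side with no co-oriented Chi strictly between; exact ties resolve toward
  the GCS (deterministic). The complementary `upstream_gcs` flag supports
  the active- vs inactive-orientation comparison.
* **relative-density enrichment** — per Chi site, co-oriented-strand
  density in each library is RPKM-scaled, smoothed (1 kb), stabilized with
  a pseudocount of one read per smoothing window, divided (+Cfx / control)
  and averaged over offsets 0 to +5 kb. Smoothing before division is what
  makes a per-base ratio well defined at these depths. Group means are
  compared with a two-sided Welch t test (the unequal-variance form, since
  nothing guarantees equal spread between classes) plus a seeded
  label-permutation test; the permutation orders sites canonically by value
  first, so its p value is invariant to site ordering and survives the
  flip-symmetry check bit-for-bit.

## Numerical and degenerate-input choices

Zero-read libraries are errors, not NaNs (`empty library`). Identical
constant enrichment groups (both variances zero, equal means) report
`t = 0, p = 1` rather than failing, matching the obvious limit. Offsets
with no contributing anchors propagate `NA` and are excluded from means.
Smoothing at profile edges uses partial symmetric windows. All RNG passes
through `withr::with_seed`, with sub-seeds derived arithmetically and kept
below 2³¹.

## What the null test means by "within 3σ"

On simulated libraries with all modifiers at unity, the normalized Chi
metaplot should be 1 up to sampling noise. The per-offset sampling sd of
the smoothed profile follows from Poisson counting,
`σ = 1 / sqrt(λ₀ · n_anchors · span)`, with λ₀ the per-base, per-strand
background rate. A metaplot has ~250 effectively independent smoothed
offsets, so demanding |profile − 1| < 3σ *pointwise* would fail roughly
half of all null replicates by multiplicity alone. The null check therefore
uses a simultaneous band at the familywise two-sided 3σ level (Bonferroni
over the effectively independent offsets, z* ≈ 4.4), the calibrated
rendering of "flat at the 3σ level at every offset". Null replicates run on
a 300-kb genome with 4×10⁵ reads and 16 Chi sites — sizes chosen so the
band is a few percent wide while ten replicates stay cheap.

## Known limitations

* The exact aligner is deliberate: guides are short and mismatch-free
  alignment is the defining filter, but reads from unsequenced variants or
  with sequencing errors are simply lost.
* The real masked-region list for the published Chi census (termination
  region plus rRNA operons and other high-signal regions) is only partially
  specified in the main text; the census check masks the stated 1.2–1.7 Mb
  termination region and is expected to be sensitive to the remainder.
* The drop statistic takes a minimum of a noisy curve and is therefore
  biased upward by selection at low depth (≈ +2–5 percentage points at the
  default study conditions); the recovery tolerance (±5 points) absorbs
  this, and the bias vanishes as depth or anchor count grows.
* Rolling-window profiles are anchored at coordinate 0; their step grid is
  not symmetric under genome reversal (window *sums* are, as the strand
  swap test shows), so the flip-identity check covers the scalar and
  anchored statistics.
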