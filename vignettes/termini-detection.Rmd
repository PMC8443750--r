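---
title: "Detecting phage genome termini and packaging mechanisms from virome reads"
author: "phageTermini"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage genome termini and packaging mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageTermini)
```

## The signal and its physical origin

A phage particle packages a linear DNA molecule. When a sequencing
library is built by ligating adapters to randomly fragmented DNA, the
fragmentation points are uniform along the molecule — but the two
molecule ends are not random: every single virion contributes a fragment
that terminates exactly at each natural end. After mapping reads back to
an assembled contig, the count of reads whose 5' base lands on position
$i$ of strand $s$ (the starting-position coverage, $\mathrm{SPC}_s(i)$)
is therefore flat at the fragmentation rate everywhere except at
termini, where it spikes in proportion to the number of particles in the
sample.

The method only works when library preparation preserves natural DNA
ends (mechanical shearing/ligation protocols). Tagmentation-based
libraries insert adapters with their own sequence bias and are
incompatible with this analysis.

## Mapping model

Reads are anchored by their first $k$ bases (default $k = 20$), matched
*exactly* against an index of every $k$-mer of every contig's forward
strand. An occurrence of the seed at position $p$ is a candidate start
$(\text{fwd}, p)$; an occurrence of the seed's reverse complement at $q$
is a candidate start $(\text{rev}, q + k - 1)$, the coordinate of the
read's 5' base. Three deliberate choices:

* **Exact seeds, first bases only.** The terminus signal lives in the
  read's first base; a mismatch there destroys the evidence anyway, and
  exact matching keeps the mapper trivially verifiable against a
  brute-force scan (which the test suite does).
* **Within-contig ambiguity discards the read for that contig.**
  Fractional assignment of repeat-region reads would fabricate SPC
  peaks. A consequence is the conservation law
  $\sum_i \mathrm{SPC}_{fwd}(i) + \mathrm{SPC}_{rev}(i) = n_\text{used}$,
  enforced as a class invariant.
* **Cross-contig multi-mapping is allowed.** Each contig is treated as
  an independent candidate genome: a terminus must remain discoverable
  when assembly variants share sequence.

$k$-mers containing N are never indexed, so assembly ambiguity cannot
create matches. Mates of a pair are mapped as independent reads; both
carry start information (R2's 5' base is the fragment's *other* end).
Coverage is the read span extended from the start coordinate, clipped at
contig bounds; contigs are linear, seeds never wrap the origin, so a few
positions near the contig edges have depressed coverage — the statistic
below conditions on local coverage, keeping edge peaks detectable.

## Null model and peak calling

At a position covered by $c$ reads on one strand, under random
fragmentation each covering read starts at that exact position with
probability $1/\bar{\ell}$, where $\bar{\ell}$ is the mean mapped read
length. So

$$\mathrm{SPC} \mid c \;\sim\; \mathrm{Binomial}(c,\, 1/\bar{\ell})$$

and the p-value is the exact upper tail $P(X \ge \mathrm{SPC})$. This is
the simplest model that normalises read starts against whole-sequence
coverage, and conditioning on $c$ makes it robust to coverage
heterogeneity between and within contigs.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `minCov` | 10× | positions below this per-strand coverage are *untested* (not tested-and-failed), so they neither produce untrustworthy calls nor dilute the FDR correction; calls below ~10× should not be trusted |
| `alpha` | 0.01 | Benjamini–Hochberg FDR level, applied across all tested positions of one contig, both strands pooled — contigs are independent genome hypotheses, so pooling across contigs would couple unrelated phages |
| `tauMin` | 0.1 | minimum $\tau = \mathrm{SPC}/c$: at extreme coverage, biologically meaningless excesses become formally significant; the gate also sets the sensitivity floor for pac sites, where only series-initiating molecules (~1 in `seriesLen`) start at pac |
| `mergeWindow` | 20 bp | significant candidates within this window on one strand are one peak, represented by the maximal-SPC position (ties: smaller coordinate, for determinism) |

The best surviving representative per strand (smallest $q$, then larger
SPC, then smaller position) is the candidate terminus; remaining
representatives are reported as secondary peaks — in real phages these
can be secondary terminase cutting sites. Unequivocal detection
typically needs mean coverage around 30×; contigs whose mean coverage is
below `minCov` are flagged `low_coverage` and, with no peaks, classified
`LOW_COVERAGE` with a warning inviting manual inspection rather than
silently reported as negative.

## From peak geometry to packaging mechanism

Let $\Delta$ be the signed distance from the forward primary peak $a$ to
the reverse primary peak $b$ (linear coordinates). The decision list:

1. low coverage and no peaks → `LOW_COVERAGE`;
2. no peak on either strand → `NO_SIGNAL` (T4-like headful packaging
   from random positions produces no shared end);
3. a peak on exactly one strand → `HEADFUL_PAC`, that peak is the pac
   site; only series-initiating molecules share it, so its $\tau$ is
   characteristically well below 1;
4. peaks on both strands:
   * $0 < \Delta \le$ `maxOverhang` → `COS_5P`, overhang $\Delta$. The
     sign convention encodes the geometry of staggered nicks on linear
     packaged DNA: top-strand cut left of the bottom-strand cut leaves
     protruding 5' ends.
   * the mirrored case → `COS_3P`, overhang $-\Delta$;
   * $\Delta = 0$ → `AMBIGUOUS` ("blunt or unresolved cos polarity");
   * `maxOverhang` $< \Delta \le$ `maxDtr` → measure the coverage
     elevation of $[a, b]$ against the flanks (guard band
     `mergeWindow`); elevation $\ge$ `dtrRatioMin` → `DTR` with repeat
     length $\Delta$, otherwise `AMBIGUOUS` with both peaks reported;
   * anything else → retry the arc through the contig origin (a
     circularly permuted contig can place the termini region astride
     the origin), then `AMBIGUOUS`.

`maxOverhang` = 20 bp separates cos overhangs (biologically ≤ ~20 nt)
from DTRs; `maxDtr` = 10 kb bounds the repeat search. `dtrRatioMin` =
1.4 is deliberately below the ideal 2.0 of a once-per-end repeat:
assembler behaviour and coverage noise push the ratio down. In practice
the measured ratio often *exceeds* 2, because the terminal read stacks
(the SPC spikes themselves) sit inside the measured interval and add
coverage; the threshold is a lower bound, so this only adds margin.

Every input yields exactly one label — classification is total, and
failures surface as warnings, never as errors.

## Coordinate conventions

Internally all positions are 0-based half-open; every user-facing report
is 1-based inclusive. The reverse-strand SPC coordinate is the read's 5'
base, i.e. the *rightmost* contig position of its alignment, which is
what makes $\Delta$ interpretable as an end-to-end distance. Under the
shared coordinate contract, a 5' cos phage cut at $t$ with overhang $o$
has its truth peaks at $t$ (forward) and $t + o$ (reverse); a DTR phage
with repeat $r$ starting at $t$ has peaks at $t$ and $t + r - 1$, so the
reported repeat length ($\Delta = r - 1$) is one below the repeat's base
count — well within the `mergeWindow` tolerance any repeat-length
consumer must allow anyway.

## What the simulator emulates — and what it does not

`buildMockVirome()` generates, per phage: an i.i.d. random genome at a
chosen GC; packaged molecules encoding the mechanism at coordinate
level; and paired 2×75 bp reads from an explicit fragmentation of every
molecule (successive Normal(400, 100) fragment lengths, terminal
fragments ending exactly at molecule ends), pooled and shuffled under
one run seed. Explicit fragmentation matters: it reproduces the physical
enrichment in which one fragment in roughly (molecule length)/(mean
fragment length) begins exactly at the left terminus — drawing fragment
starts uniformly over all positions would yield essentially no terminus
signal and would not emulate a ligation library.

Mechanism specifics:

* **cos** molecules span the circle from the forward truth terminus to
  the reverse truth terminus inclusive; overhangs are modelled at
  coordinate level (short-read libraries blunt the physical overhangs
  anyway — the peak offset, not the single-strandedness, is the
  observable).
* **DTR** molecules carry the repeat at both ends; the emitted reference
  contig is *collapsed* (repeat present once), reproducing what
  assemblers hand the detector.
* **HEADFUL_PAC** packages series of `seriesLen` (default 4) headfuls of
  `headfulFactor` (default 1.03) genome lengths. Only the
  series-initiating pac cut is exact; subsequent headful boundaries get
  Gaussian jitter (`headfulJitterSd`, default 1% of the genome),
  reflecting the documented imprecision of capsid-fill measurement. The
  defaults make the pac peak carry ~25% of molecule left ends — a
  realistic weak-peak regime.
* **HEADFUL_RANDOM** starts each headful uniformly on the circle — the
  negative control class.

Not emulated: indel and quality-model errors, GC-coverage bias, chimeric
reads, host contamination, Mu-type host-DNA ends, and real assembler
artifacts (misassemblies, fragmented genomes). Passing the simulation
suite therefore demonstrates the statistical machinery and the
geometry-to-mechanism logic under ideal mapping conditions; it does not
certify behaviour on low-complexity genomes, heavily repeated termini
regions, or libraries whose fragmentation deviates from uniformity.

## Problem sizes and numerical choices

The validation suite runs a pooled five-phage mock virome of 40 kb
genomes at 2×10⁴ read pairs per phage (~75× coverage) — the same
composition as the classical Lambda/HK97/T7/P1/T4 reference panel — plus
100 random-headful 10 kb contigs at ~30× for false-positive control, 20
seeded simulations per mechanism at ~30× for recovery rates, and
brute-force cross-checks of the mapper (naive all-position scan) and of
the p-values (direct pmf summation, agreement to 1e−12 for all coverages
≤ 30). These sizes give stable statistics (terminal SPC ≈ 200 on the
mock, against a background start rate of ~0.5 per position) while
keeping a full run in minutes on one core.

Ties and degeneracies are resolved deterministically everywhere (max
SPC, then smallest coordinate; BH within contig; stable contig order),
and the per-contig stage is embarrassingly parallel, so `report.csv` is
byte-identical for any worker count and any read order — a property the
suite asserts.

## Known limitations

* Sensitivity falls with coverage; below ~10× mean coverage most
  positions are untestable and the contig is flagged rather than
  classified.
* Exact seeding loses reads with an error in their first 20 bases; at
  typical short-read error rates this costs a roughly constant fraction
  of the signal and does not bias peak positions, but very high error
  rates (long-read raw data) need a shorter seed or upstream
  error correction.
* A pac site falling in repeated sequence is invisible (ambiguous reads
  are discarded).
* Blunt-ended cos phages ($\Delta = 0$) cannot be distinguished from a
  coincident two-strand artifact and are reported `AMBIGUOUS` by design.
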