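---
title: "Detecting repeat-mediated recombination in plant mitochondrial genomes"
author: "mitorecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated recombination in plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The biological problem

Plant mitochondrial genomes are conventionally assembled and deposited as a
single circular "master circle", but in vivo they interconvert between the
master arrangement and a set of alternative arrangements generated by
homologous recombination across dispersed repeat pairs.  A **direct** repeat
pair (two copies in the same orientation) splits the master circle into two
subgenomic circles, each retaining one repeat copy; an **inverted** pair (one
copy and its reverse complement) inverts the intervening segment.  Long reads
decide between arrangements: a read that crosses a repeat copy with alignable
sequence in *both* flanks is consistent with exactly one junction and
therefore supports exactly one conformation.  Counting such spanning reads
per repeat yields a support fraction, and repeats with substantial
alternative support imply a multipartite genome model.

`mitorecomb` implements this analysis end to end on circular molecules:
repeat discovery (SSRs, tandem arrays, dispersed pairs), junction
enumeration, read classification, support tallies, multipartite inference,
plus two companion analyses commonly reported alongside it — pairwise
shared-DNA fractions between genomes and detection of plastid-derived
fragments (MTPT) — and a fully ground-truthed synthetic data generator used
by the test suite.

## Circular coordinates

All molecules are `circular_seq` objects with wraparound semantics: interval
extraction, repeat scanning, homology search and coverage union all treat
position `L + 1` as position 1.  Internally every scanner works on the
doubled sequence and collapses records to canonical coordinates
(`start` in `1..L`; `end` may exceed `L` for features straddling the
origin).  Reports use 1-based inclusive coordinates; BED output is 0-based
half-open with wrapped features split at the origin.

## Repeat detection

**SSRs.**  Maximal perfect runs of primitive 1–6 bp motifs, at or above the
copy-number minima conventional for organelle surveys (10, 5, 4, 3, 3, 3 for
mono- through hexanucleotide units).  Motifs are canonicalized to the
lexicographic minimum over rotations; runs containing `N` are excluded; a
partial trailing copy is trimmed so that `end - start + 1` equals
`unit length x copy number`.  The scanner is validated against an
independent regular-expression oracle (overlapped lookahead matches plus a
left-maximality filter).

**Tandem repeats.**  Candidate arrays are found by recurring k-mers at a
constant spacing (the candidate period, capped at 500 bp), extended while
the sequence remains periodic, and scored against their own majority
consensus with a wraparound dynamic program under the weights +2 per match
and −7 per mismatch or indel; arrays scoring below 50 are suppressed.  A
perfect array therefore scores twice its length, which gives convenient
closed-form expectations in tests (30 copies of `AT` score exactly 120; 12
copies score 48 and are rejected).

**Dispersed repeat pairs.**  A word-size-7 seeded self-comparison with
maximal ungapped extension, on both strands of the doubled molecule,
filtered at ≥ 100 bp and ≥ 90% identity by default.  We deliberately do not
reproduce BLAST's E-value machinery: an E-value depends on Karlin–Altschul
statistics of the scoring system and database size, which makes acceptance
thresholds irreproducible across implementations, whereas a length plus
identity filter is deterministic and directly testable.  With
`min_identity = 1` the extension is exact and the output is provably the
set of maximal exact repeated pairs, which is what the O(n²)-style oracle
in the test suite enumerates by fixed-string search.  Overlapping repeat
families are reported as distinct pairwise records without clustering.

## Conformation enumeration and read classification

For a repeat pair with copies written in the orientation of copy 1, every
junction has the structure (left flank, repeat, right flank).  With flanks
`LA/RA` around copy 1 and `LB/RB` around copy 2 (reverse-complemented for
inverted pairs), the master junctions combine `(LA, RA)` and `(LB, RB)` and
the recombinant junctions exchange them: `(LA, RB)` and `(LB, RA)`.  This
reduces direct and inverted pairs to a single classification rule.  Flanks
default to 1000 bp and are truncated to the shorter inter-repeat arc, so
that each junction reference is always an exact substring of its
conformation molecule — a property the test suite verifies against an
independent cut-and-join oracle on 100 random genomes.

A read is classified by (1) locating the repeat on the read with exact
13-mer seeds in either orientation, (2) extrapolating the repeat boundaries
on the read from the seed diagonals, and (3) aligning the read segments
immediately up- and downstream of the repeat against both candidate flanks
with a fitting alignment.  A side is resolved only when exactly one flank
reaches the identity threshold over the anchor length; reads failing
placement, touching one flank only, or consistent with both conformations
are counted **uninformative**, and support fractions are computed over
informative reads only.  The anchor defaults to 100 aligned bases per flank
at ≥ 85% identity: at long-read error rates around 5% a true flank aligns
near 90% identity while an unrelated flank aligns near 55%, so the
threshold separates the two by a wide margin; 100 bp anchors make chance
resolution at that threshold negligible.

Support fractions are rounded half-up to 2 decimals.  Published tables of
this kind occasionally truncate (62% for 16/26); we report consistent
2-decimal values instead and verify the raw-count arithmetic exactly.

The alignment backend is pluggable in the sense that classification
consumes only junction references and flank alignments; the built-in seeded
aligner is the default and the only backend exercised by the tests.

## Multipartite inference

Repeats at or above the activity threshold (default 20% alternative
support) are marked recombinationally active.  The threshold sits midway
between the two empirical regimes seen in long-read surveys of plant
mitogenomes — roughly balanced support at active repeats versus a few
percent recombinants at inactive ones — and is configurable.  For each
active direct repeat the model reports the two subgenomic circles produced
by pairwise surgery (sizes provably summing to the master length, each
master base in exactly one segment set); for an active inverted repeat, the
inverted-segment circle of unchanged length.  Circles are enumerated per
repeat independently; when the copies of two active direct repeats
interleave, their joint products are combinatorially ambiguous and the
model flags this instead of resolving it.  The model describes the
assembly's read support, not a claim about in vivo stoichiometry.

## The synthetic data generator

`sim_genome_spec()`/`build_genome()` construct a circular mitogenome with
an i.i.d. background at a specified GC fraction, planted direct/inverted
repeat pairs (copy 2 copied from copy 1), and MTPT segments present
identically in a companion plastid molecule.  Colliding plants are rejected
by name.  `read_sim_spec()`/`simulate_reads()` draw reads from a weighted
mixture of the master circle and alternative-conformation molecules, with
log-normal lengths (default meanlog `log(20000)`, sdlog 0.6, floored at
200 bp — a long-read profile with a heavy tail) and i.i.d. substitutions
and single-base indels.  One integer seed governs genome and reads and is
recorded in the FASTA headers; identical specs give byte-identical output.

What the generator emulates: genome scale (hundreds of kb), repeat sizes
from ~100 bp to several kb, MTPT sizes of roughly 115–887 bp, mixtures of
conformations, and realistic per-base error.  What it does not emulate:
compositional heterogeneity, homopolymer-biased errors, chimeric reads, and
sequence-divergent repeat copies.  Passing tests therefore demonstrate the
correctness of the algorithms under the stated model, not robustness to
every artifact of real sequencing runs.

Read-length default and power: a classifiable read must span
repeat + 2 anchors, so for multi-kb repeats only reads many kb long are
informative.  The default length profile was chosen so that a
1000-read junction-spanning pool yields several hundred informative reads,
for which the binomial standard error of a support fraction is below 2
points — the precision needed for ±5-point recovery checks to be a
property of the method rather than of sampling noise.  For the same reason
the recovery experiments simulate reads with `focus = "junctions"`
(uniform over windows upstream of each junction, symmetrically across
conformations, which leaves the support estimator unbiased), mirroring the
junction-reference alignment design of the underlying analysis; uniform
whole-genome simulation is the default and is what the end-to-end pipeline
test uses.

## Homology and MTPT

`pairwise_homology()` applies the same seeded ungapped search between two
molecules on both strands.  Shared-DNA summaries report the width of the
overlap-merged union of segment intervals on each genome, as a percentage
of that genome's own length (2 decimals, half-up).  `find_mtpts()` is the
mito-versus-plastid specialization; totals are computed on merged
mitochondrial intervals so nested fragments are not double counted.  The
ungapped extension is adequate for identifying near-identical transfers and
planted ground truth; strongly diverged homology tracts that require gapped
alignment are outside this package's scope and are the main known
limitation of the homology module.  Synteny-block ordering (Mauve-style
locally collinear blocks) is deliberately out of scope; only the shared
kb/percent statistic is computed.

## Genome statistics and reporting

`summarize_annotation()` accepts GFF3 (via rtracklayer) or a GenBank flat
file (a minimal built-in feature-table parser) and computes feature counts,
coding and structural-RNA base totals as unions of exon intervals
(overlapping genes are never double-counted, so fractions cannot exceed
100%), intron counts as exons − 1 summed over multi-exon genes, and a
functional class table keyed by conventional mitochondrial gene name
prefixes.  Fractions are computed from first principles from these unions.
`run_pipeline()` drives the whole analysis from one configuration list or
YAML file and renders a single Markdown report; outputs are byte-stable
under a fixed seed (stable ordering, fixed rounding, no timestamps in
outputs — timings go to the message stream).

## Numerical and design choices

* Rounding: all reported percentages use half-up rounding at 2 decimals
  (`floor(x * 100 + 0.5) / 100`), never banker's rounding.
* Degenerate tallies: a support fraction with no informative reads is `NA`,
  not 0/0; an all-`N` sequence has `NA` GC content.
* Tie-breaks: tandem candidates are deduplicated by score, then smaller
  period (so a primitive period beats its multiples); dispersed records
  contained in a longer record on the same pairing are dropped.
* Problem sizes in the shipped tests: oracle equivalence on 100 kb (SSR)
  and 5 kb (dispersed) sequences, 100 junction-surgery toys, recovery at
  20 replicates x 3 mixtures x 1000 reads on a 200 kb circle, and an
  end-to-end 60 kb pipeline fixture run twice for byte-stability.  These
  sizes exercise every code path at full fidelity while keeping the suite
  fast enough to run routinely.
* Seeds: every stochastic step takes an explicit integer seed and restores
  the RNG state afterwards (`withr::with_seed`), so library use never
  perturbs a session's RNG.

## Worked example

```{r example, eval = FALSE}
spec <- sim_genome_spec(
  genome_length = 200000,
  repeats = data.frame(length = 5000, start1 = 30001, start2 = 120001,
                       orientation = "direct"),
  seed = 11)
g <- build_genome(spec)$mito

pairs <- find_dispersed_repeats(g)
cs <- enumerate_conformations(g, pairs[1, ], F = 1000)

rspec <- read_sim_spec(weights = c(master = 0.5, R1 = 0.5), n_reads = 1000,
                       sub_rate = 0.025, ins_rate = 0.0125,
                       del_rate = 0.0125, seed = 12)
reads <- simulate_reads(g, list(cs), rspec, focus = "junctions")

cl <- classify_reads(reads, cs)
support <- support_table(list(R1 = cl$label), pairs)
model <- infer_multipartite(support, g, pairs)
print(model)
```

## Known limitations

* Ungapped homology extension (no gapped tracts); adequate for
  near-identical repeats and transfers only.
* No joint modeling of simultaneous recombination across several repeats;
  interleaved active pairs are flagged, not resolved.
* The tandem-repeat module targets arrays detectable through exact k-mer
  recurrence; heavily diverged arrays below ~80% internal identity may be
  missed.
* Classification assumes repeat copies are near-identical (as planted by
  the simulator); paralogous copies diverged enough to align distinctly
  would allow a more direct assignment that this package does not attempt.
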