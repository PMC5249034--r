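---
title: "Finishing bacterial draft assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing bacterial draft assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finishr)
```

## The problem

A bacterial sequencing project typically ends its *de novo* assembly stage
with tens to hundreds of contigs from a single circular chromosome of a
few megabases. Finishing turns that pile into a complete genome: the
contigs must be ordered and oriented, their coordinate start must agree
with a community convention (the replication start of the reference),
redundant contig ends must be merged, and the sequence missing between
neighbours must be recovered. finishr implements this flow against two
ordering axes — a related reference genome, or an ordered
restriction-fragment ("optical") map of the chromosome — with a
read-pileup consensus supplying the gap sequence.

## The alignment engine

Every step rests on local alignment, so the package ships its own
seed-and-extend engine rather than shelling out to an external aligner:

* **Seeding.** All maximal exact word matches of length ≥ `word_size`
  (default 11) between query and subject are enumerated from a hashed word
  index; word hits on one diagonal that overlap are fused into exact runs.
* **Chaining.** Runs are clustered greedily by subject position and
  diagonal (diagonal tolerance 100 bp, chain gap 1 kb), so one homologous
  segment — even with scattered mismatches and small indels — forms one
  cluster, while distinct repeat copies form distinct clusters.
* **Extension.** Each cluster is extended by a banded affine-gap local
  Smith–Waterman over the rectangle the cluster spans (plus 100 bp of
  context), with the band taken from the cluster's diagonal range plus
  50 bp of slack. We chose a banded exact DP over the classical X-drop
  heuristic because it bounds work the same way while keeping the
  traceback exact; on homologous pairs the top hit provably equals the
  unrestricted Smith–Waterman optimum whenever the optimal alignment stays
  inside the band, and the test suite checks this equality against an
  independent implementation on hundreds of generated pairs.
* **Scoring.** blastn-like defaults: match +2, mismatch −3, gap of length
  L costs 5 + 2L. Configurable via `align_scoring()`.

Two consequences are deliberate. First, homology that shares no word of
`word_size` bases is invisible — contig overlaps shorter than 11 bp are
therefore never merged, which reproduces the behaviour of word-based
aligners used in this role. Second, `best_anchor()` refuses to anchor a
flank when the two best hits lie at distinct loci and score within 5% of
each other (`ambiguity_margin`): an ambiguous anchor, e.g. inside a
repeat, is treated as no anchor at all, because anchoring a gap flank to
the wrong repeat copy would silently fabricate genome structure.

Deterministic tie-breaks everywhere: hits sort by score, then lower
subject start, then lower query start, then `+` before `-`.

## Scaffolding

`order_contigs_by_reference()` aligns each contig, chains its hits by
locality and strand, and places the contig iff the best chain covers at
least `min_coverage_frac` (default 0.4) of its length and no rival chain
at another locus scores within the ambiguity margin. Placement
coordinates are projected from the chain's dominant hit — not from the
chain's extreme coordinates — so a short spurious repeat hit swept into a
chain cannot corrupt the placement. Contigs shorter than `min_contig_len`
(200 bp) or failing the rules are returned as `unplaced`, never dropped.

Gap sizes come from axis distance (`max(next_start − end, 1)`); an
apparent overlap is floored to a 1 N spacer and flagged as a candidate
merge. Whether inter-contig gaps should instead use a fixed spacer is
genuinely open (the optical-map report may carry no usable distance), so
both policies exist; `fixed` uses 100 N, the convention for
unknown-length gaps in public archives. AGP v2.1 output converts the
package's uniform 0-based half-open coordinates to 1-based inclusive at
the boundary; gap lines carry linkage evidence `align_genus` (reference
axis) or `map` (optical axis).

The optical-map path consumes a documented five-column TSV (contig, map
start/end, strand, rank). The vendor report format of optical-map
software is proprietary and undocumented, so this dialect is the
package's canonical input; it includes coordinates because gap sizing
needs them, and converting a vendor export to it is a one-liner for the
user.

## Restriction digestion and map concordance

`digest_sequence()` cuts at every forward-strand site occurrence
(overlapping occurrences included) offset by the enzyme's cut position;
linear molecules yield n+1 fragments, circular ones n fragments starting
at the smallest cut. KpnI (`GGTACC`, cut after base 1) is the built-in
default — the enzyme used in the whole-genome mapping workflow this
supports — and any enzyme is definable.

`map_concordance()` digests a scaffold in silico and compares the
fragment list against the experimental map positionally, in order:
fragments match when their relative size difference is ≤ 10%
(`size_tolerance`); fragments spanning an N gap get doubled tolerance
because their in-silico size inherits the gap estimate's uncertainty.
Circular lists are first canonicalized to their lexicographically minimal
rotation, which makes the score invariant under rotation of either map.
Positional matching (both pointers advance on a mismatch) was chosen over
resynchronizing variants because it makes the score's meaning simple —
one perturbed fragment costs exactly one match — at the price of being
conservative when fragment counts differ.

## Curation

**Origin.** `set_origin()` anchors the first `probe_len` (2 kb) of the
reference on the doubled genome (so wrap-around hits are found), treating
positions equal modulo genome length as one locus for the ambiguity rule.
A minus-strand anchor triggers reflection before rotation. The output is
a pure rotation/reflection — no base is altered — and the operation is
idempotent.

**Merging.** Adjacent contigs are merged only on a *dovetail* hit between
the left contig's 3 kb tail and the right contig's 3 kb head: the
alignment must reach the left end and the right start within `end_slack`
(10 bp), span ≥ `min_overlap` (20 bp) and have identity ≥ 0.95. Interior
repeat matches between neighbours never license a merge. The left
contig's copy of the overlap is kept verbatim — no consensus of the two
copies — because a deterministic, inspectable merge beats a silent
majority vote between exactly two observations. Merging iterates to a
fixed point.

**Gap closing.** For each junction the flanks (3 kb, taken *after*
orientation) are anchored on the reference (targets A, B); the reference
window spanning both anchors plus `pad` (500 bp) of context is cut out;
reads are mapped into the window; the flanks are re-anchored on the
resulting consensus (targets C, D); and `consensus[C_end, D_start)` is
the fill. The 500 bp pad is there so reads near the window edges still
have full-length context to align against. Status is `closed` only when
the fill has no N and every base has depth ≥ `min_depth` (3 — a minimal
guard against single-read chimeras); depth failures are N-masked and
reported `partial`; a missing, ambiguous, strand-discordant or
out-of-order anchor yields `unresolved` with the reason recorded. When
anchors land on different strands the gap is marked unresolved rather
than guessed: the pipeline orients contigs before closing, so discordant
anchors signal real trouble (misplacement or inversion), not a case to
repair silently.

**Read mapping.** The built-in mapper places each read at its best
seed-vote location (15-mer seeds, both strands), aligns it locally to
that window, and keeps it if identity ≥ 0.8 over ≥ half of its mappable
span. The consensus takes the majority base per template column (ties
resolve to the template base; a majority deletion drops the column);
insertions are accepted when more than half of the junction-spanning
reads carry one. Columns without coverage emit the template base at depth
0 — the depth vector, kept in step with the consensus through an explicit
column map, is what downstream status calls consume, so uncovered
template sequence can never masquerade as read-supported fill. The
mapper's contract is template in, consensus + depth out; any external
mapper honouring it could be swapped in.

## Synthetic data

The generators emulate the study conditions this package targets: a
circular bacterial chromosome (supplying GC content and optional planted
exact repeats), fragmentation into contigs with known placements and
junctions (gaps 200–800 bp, overlaps 50–300 bp, optional
reverse-complementing and shuffling; the truth record re-assembles the
genome exactly and self-checks at generation time), single-end ~200 bp
reads with an indel-dominant error profile (1% indels, 0.2%
substitutions; insertions duplicate the current base, mimicking
homopolymer miscalls of semiconductor sequencing), and optical maps with
3% multiplicative fragment-sizing noise and fragments < 500 bp merged
leftward (small fragments go unobserved in real optical maps). Every
generator is a pure function of its parameters and an explicit seed.

Tests run at tens-of-kilobases scale — 50 kb genomes, 8 contigs, 30×
coverage — rather than megabase scale; this exercises every code path
(the algorithms are scale-free) while keeping the suite quick. What the
synthetic model does *not* emulate: real mis-assembled contigs, chimeric
reads, coverage bias, IUPAC ambiguity codes beyond N, plasmids or other
replicons sharing the read pool, and diverged (rather than identical)
repeat families. Passing tests therefore demonstrate correctness of the
machinery, not robustness to every pathology of real drafts; the
ambiguity rules above are the package's main defence in the field.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based inclusive happens only in AGP output.
* Non-ACGTN characters are squashed to N on input (with a warning count)
  rather than rejected: drafts do contain IUPAC codes, and the pipeline
  only distinguishes known from unknown bases.
* Seed words occurring more than 5000 times in a subject are skipped
  (repeat guard); whole-assembly comparison uses 15-mers, where chance
  word matches are ~250× rarer than at 11.
* Zero alignment hits, zero merges, an empty read set, and unresolvable
  gaps are all ordinary outcomes, reported as empty tables or `unresolved`
  rows — not errors. Hard errors are reserved for contract violations:
  duplicate ids, malformed files, no contig placed at all.
* The pipeline proper contains no randomness; reruns are byte-identical.
  Only the synthetic generators take seeds.

## Limitations

* One ordering axis per run; multi-replicon projects (chromosome +
  plasmids) must be finished per replicon.
* Repeats longer than the flank length defeat anchoring by design; such
  gaps stay `unresolved` for manual curation rather than being guessed.
* The merge keeps the left overlap copy; disagreements between the two
  copies are logged but not reconciled.
* Frameshift correction and free-form manual editing are out of scope;
  the outputs (AGP + FASTA + reports) are meant to feed such tools.
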