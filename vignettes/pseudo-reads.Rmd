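---
title: "Connecting read pairs through a Bloom filter de Bruijn graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connecting read pairs through a Bloom filter de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(konnector)
```

## The problem

Paired-end tag (PET) sequencing reads both ends of a DNA fragment. When
the fragment is longer than the two reads combined, an unsequenced gap
remains between the mates. With redundant coverage, the gap can be
filled by local *de novo* assembly: the read set implies a de Bruijn
graph (nodes are k-mers, edges are k−1 base overlaps), and the interior
of the fragment is a path in that graph between the two reads. The
package reconstructs such fragment-length "pseudo-reads", optionally
extends them outward as far as the graph is unambiguous, and applies
the same machinery to close N-gaps in draft assemblies.

## The graph: a two-level Bloom filter

Storing an explicit graph for billions of k-mers is prohibitive, so the
node set is held in a Bloom filter — a bit array addressed by `h` hash
values per key, with no false negatives and a false-positive rate of
approximately $(1 - e^{-hn/m})^h$ for $n$ keys in $m$ bits. Edges are
never stored: the neighbours of a node are found by querying the four
possible single-base extensions on either side. K-mers are
canonicalized (the lexicographic minimum of the word and its reverse
complement), so membership is strand-symmetric; traversal nevertheless
carries the *oriented* word, so "left" and "right" are well defined
even at palindromic k-mers.

Sequencing errors would litter the graph with spurious nodes, so
loading cascades k-mers through two filters: the first records k-mers
seen at least once, and a k-mer already present in the first filter is
promoted into the second. Only the second ("seen at least twice")
filter is kept after loading — singleton error k-mers never become
graph nodes. FASTQ reads are hard-trimmed at the 3' side from the first
base under Phred quality `q` (default 15) before k-merization, and
reads are split at non-ACGT symbols.

Sizing: the builder's default is 12 bits (1.5 bytes) per input base
split equally across the two levels, with `h = round(ln2 · m/n)`
(floor 1). The number of *distinct* k-mers is unknown before loading,
so total input bases — an upper bound on distinct k-mers — stands in
for `n`; at typical coverages the realized false-positive rate is well
below the 1.5-bytes-per-distinct-k-mer design point. An explicit `bits`
argument (CLI `-b`) overrides this. Filter files use a little-endian
header (`"KONBLOOM"`, version, k, levels) followed by the raw level-2
bit array, and round-trip bit-exactly; hashing uses two fixed-seed
64-bit hashes combined by enhanced double hashing, so files built from
the same reads are byte-identical.

## Anchors

A path search launched from an erroneous or false-positive k-mer dies
in a dead end. Each read therefore contributes a trusted *anchor*:
among runs of at least three consecutive graph-member ("solid") k-mers,
the run closest to the 3' (gap-facing) end is chosen — minimizing
search depth — and the anchor is the run's 5'-most k-mer, so that even
a false-positive anchor is followed by two more solid k-mers. With no
run of three, the longest run is used (ties toward 3'). Read 2's anchor
is reverse-complemented onto the fragment's forward strand to serve as
the search goal.

## The search

All connecting paths up to a depth limit matter for accuracy — a
shortest-path algorithm would silently drop alternatives — so the
search is breadth-first, bidirectional, and depth-limited. Two BFS
frontiers (forward from the start anchor, leftward from the goal)
alternate strictly, forward first; each expands at most
⌈depth/2⌉ + 1 node levels. Every edge touched by a dequeued node is
recorded in an in-memory search graph. When one frontier generates a
node the other has already visited, that edge becomes a *common edge*
and the node is not expanded further by the arriving side. The
connecting paths are then enumerated by exhaustive depth-limited
traversal of the recorded search graph; on the fixtures used in the
tests this equals a one-sided depth-limited BFS and an exhaustive DFS
oracle exactly. The depth limit is `F − offset1 − offset2 − k + 1`
nodes, so a finished pseudo-read can never exceed the maximum fragment
length `F`.

Tunables (defaults are the parameter set the tool's published
protocols use):

| parameter | default | meaning |
|---|---|---|
| `k` | — | k-mer length (bases); graph resolution |
| `B` | 100 | branch budget: dequeued fork children beyond the first, summed over both frontiers |
| `F` | 525 | maximum fragment/pseudo-read length (bases) |
| `P` | 4 | maximum alternate paths collapsed to a consensus |
| `M` | ∞ | maximum pairwise mismatches between alternate paths |
| `X` | 98 | minimum pairwise percent identity between alternate paths |
| `q` | 15 | Phred threshold for the 3' load-time trim |

The unit of `B` is not defined by the original description; here it
counts every dequeued fork child beyond the first, which makes the
budget independent of frontier scheduling.

## Consensus

A single path is used verbatim. Equal-length alternates (SNP bubbles)
are collapsed by column-wise majority vote; unequal lengths first go
through a progressive Needleman–Wunsch alignment (match +1, mismatch
−1, gap −2; traceback prefers diagonal, then up, then left — exact
alignment is affordable because `P` ≤ 10 in every protocol). Pairwise
mismatches (gap columns included) above `M`, or pairwise identity —
matching columns over non-both-gap columns — below `X`%, abort with
`paths_disagree`. Column ties prefer a base over a gap and the
lexicographically smallest base, keeping output deterministic. With
exactly two tied alternatives the vote cannot prefer either arm; the
lexicographic rule then decides, which is why a *recurrent* sequencing
error (one that appears twice and thus enters the seen-twice graph) can
win a bubble column at about half of such sites. Raising the load
threshold or `X` tightens this at the cost of yield.

The pseudo-read is read 1's 5' flank verbatim, the connecting sequence
(anchor to anchor, spelled from the graph — implicit error
correction), and the reverse-complemented read 2's 3' flank verbatim.
Read bases 5' of an anchor are deliberately not rewritten; a
substitution there survives into the output, which is visible in the
exact-match rates the acceptance checks print for the 0.1%-error
setting. The connecting region itself never inherits a
single-occurrence read error, because such k-mers cannot enter the
seen-twice graph.

## Extension, duplicate filtering, correction

With extension enabled, a connected pseudo-read is extended outward in
both directions, one base per linear step, until a dead end, an
unresolvable fork, or a revisited node. Two pieces of look-ahead logic
handle the common non-linearities:

* branches that die within **three nodes** are taken to be Bloom
  false positives and ignored (a single-base Bloom collision rarely
  finds onward neighbours, so such branches are short — unlike error
  branches, which run up to k nodes but are already excluded by the
  two-level filter);
* a fork with exactly **two** surviving branches triggers a look-ahead
  of k+1 nodes per arm; if the arms reconverge at the same position
  (the signature of a heterozygous SNP bubble), the bubble is collapsed
  and extension continues. The emitted arm is the lexicographically
  smaller one — a deterministic stand-in for an arbitrary haplotype
  choice.

There is no default cap on extension length: the algorithm's own
stopping rule is ambiguity, and a visited set of oriented words
terminates walks on circular genomes. `max_left`/`max_right` caps are
available where fragment bounds matter (inward extension of unconnected
reads is capped at `F −` read length).

Extending every pair of a deeply covered locus would emit the same
sequence thousands of times, so a second Bloom filter — the *duplicate
filter* — tracks the k-mers of everything already emitted. A connected
pair is emitted only if its connecting sequence (whose k-mers are all
graph members, so a covered locus gives a 100% duplicate hit) contains
at least one unseen k-mer; the k-mers of the full extended sequence are
then registered. Unconnected reads are first *corrected*: from the
rightmost k-mer of the read's longest solid run, the walk steps left
exactly k nodes (aborting on any branch or dead end — a single error's
branch is at most k nodes long, so this provably exits it), then right
up to k+1 nodes, keeping whatever was built when it stops early. The
corrected (≤ 2k+1 base) sequence is novelty-tested, extended inward and
outward, registered and emitted. Read 1 is processed before read 2 and
the second is tested after the first is registered; the order is fixed
for determinism. With extension off, the original behaviour is kept:
one pseudo-read per connected pair, no duplicate filter.

## Gap closing

Draft assemblies represent unresolved sequence as runs of N. The gap
closer finds all maximal N-runs (0-based half-open coordinates),
derives up to 100 bases of N-free flank on each side (trimmed at
neighbouring gaps; 100 bases accommodates the largest sweep k while
staying local), and treats flank 5' as read 1 and the reverse
complement of flank 3' as read 2. Connection is attempted over a
descending sweep of k values — one reusable filter per k, built once
for all gaps — because large k resolves repeats while small k tolerates
thin coverage; the first success wins. The protocol defaults are
`B = 1000, F = 700, P = 10`. A closure replaces the N-run together with
both flank regions, so the patched scaffold contains the closure
verbatim; a closure whose first/last k bases disagree with its flanks
is rejected with a warning, and no base outside a replaced span ever
changes. The report counts gaps total/closed and the percentage
(one decimal).

## The simulator

Validation needs exact ground truth, so the package ships the
generator that emulates the synthetic study conditions: i.i.d. uniform
ACGT genomes; fragments drawn from a normal insert-length distribution
(default 400 ± 50 bp) truncated to [2·read length, genome length] with
uniform starts; read 1 the fragment's 5' prefix and read 2 the reverse
complement of its 3' suffix (FR); i.i.d. per-base substitutions
(default 0.1%, always changing the base); pair count =
coverage · genome / (2 · read length) at default 50-fold coverage. The
truth table records each fragment's exact span, so connection output is
scored by string equality with no aligner in the loop. Substitutions
only — at these settings indels are negligible and exact-match scoring
stays meaningful; there is no quality profile, GC bias, or adapter
read-through, so passing tests say nothing about those artefacts of
real libraries. Heterozygous fixtures plant i.i.d. SNPs into a second
haplotype; masking fixtures place non-overlapping N windows (one per
equal-size block, at least the flank length from ends and neighbours)
and retain the truth. Everything is deterministic per seed on a fixed,
platform-stable RNG (Mersenne-Twister), and the generators restore the
caller's RNG state.

## Numerical and degenerate-input choices

* Identical anchors (`start == goal`) are a degenerate success: the
  pair overlaps and the connector is the anchor k-mer itself.
* A fragment longer than `F` is reported `no_path` — the depth limit is
  the definition of "too far", not a failure of the search.
* Reads shorter than k yield empty masks and `no_anchor`.
* Path enumeration allows node revisits (the depth limit bounds the
  walk), so plasmid-like cycles cannot hang the search; `P` caps the
  returned set and a hard step budget backstops adversarial graphs.
* Consensus/identity conventions, the `B` unit, and the bubble-arm
  choice are implementation-defined where the original description is
  silent; each is fixed to a deterministic rule and documented above.

## Problem sizes used in the checks

The shipped checks run at the synthetic study scale where that scale is
stated — a 20 kb genome at 50× PE100 coverage for connection and
extension, 20 random 3 kb genomes with 50 anchor pairs each for the
search-oracle equivalence, and a 100 kb genome with 20 masked windows
(50–300 bp) and a 90/70/50/40 k-sweep for gap closing — and at a few
kilobases for unit fixtures. At k = 90 and 100 bp reads the per-k-mer
coverage is only 5.5×, so the sweep's first element rarely closes a gap
and the fall-through to k = 70 and below is exercised for real.

## Known limitations

* Flank bases outside the anchors are emitted verbatim (see above);
  quality-aware flank polishing is not attempted.
* Recurrent errors (the same substitution sighted twice) can enter the
  graph and, in an exactly-two-path tie, win the consensus column.
* The bidirectional frontier-sealing rule can, on graphs with dense
  shortcuts, hide a path that weaves repeatedly between the two
  frontiers' territories; on read-like graphs the enumeration equals
  the exhaustive oracle, which the tests verify.
* Execution is single-process; the `-j` flag is accepted for
  compatibility and never changes output.
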