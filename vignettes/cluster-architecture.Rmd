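---
title: "Encoding and analysing swainsonine cluster architecture"
author: "swnsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and analysing swainsonine cluster architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swnsyn)
```

## The problem

The swainsonine (SWN) biosynthetic cluster comprises up to seven genes —
*swnK*, *swnH1*, *swnH2*, *swnN*, *swnR*, *swnT*, *swnA* — and its internal
architecture differs strikingly between the fungi that carry it: genes are
missing, neighbouring pairs are swapped or inverted, and intergenic spans
range from a few nucleotides to over two kilobases.  `swnsyn` treats that
architecture itself as phylogenetic data.  This vignette describes the
model behind each stage, the parameters that matter, the numerical
decisions taken where the design was genuinely open, and what the
simulator-based tests do and do not establish.

## Adjacency characters and orientation typing

A cluster layout is one taxon's ordered, stranded gene annotations on a
single contig (1-based inclusive coordinates throughout, the GFF3
convention; the TSV dialect uses the same to avoid mixing conventions).
Each pair of coordinate-consecutive SWN genes is an *adjacency*; the
unordered pair defines the character and the intergenic span runs from one
past the left gene's end to one before the right gene's start, with
negative spans recorded as overlaps of length zero.  Intervening non-SWN
genes are retained on input but ignored by adjacency derivation: the
cluster genes are the gene universe and anything between them is treated
as intergenic content.

Thirteen canonical characters, numbered 0–12 starting at *swnH2–swnK*, are
fixed by the curated 14-taxon table; novel pairs in user data receive
fresh stable ids from 13 upwards, registered in their observed orientation
(the first observer of a novel pair is type A by construction).

Orientation calls need a polarity convention, and none is derivable from
the raw coordinates alone: annotations arrive on arbitrary strands of
arbitrary assemblies.  We orient every cluster so that its
highest-priority anchor gene lies on the plus strand, with priority
*swnK* > *swnH2* > *swnR* > *swnN* > *swnH1* > *swnT* > *swnA*.  The
choice of *swnK* as primary anchor is deliberate: it is the one gene
present in every taxon (it is the inclusion criterion for the survey), so
the convention applies uniformly, and it makes the published A/B examples
come out as printed.  The operation mirrors coordinates about the occupied
span, flips strands and reverses order, and is idempotent.  Per-gene
strand disagreements after orientation do not enter the typing — the
orientation of a whole intergenic region, not of individual genes, is what
the A/B distinction describes.

An organism is typed A (all adjacencies canonical), B (all inverted) or
A/B (mixed).  Two of the fourteen curated organisms are labelled pure B at
the organism level without per-cell inversion marks in the source table;
the fixture carries the organism-level label verbatim and does not invent
per-cell flags beyond it.

## The curated tables

The two packaged fixtures are hand-transcribed, pre-parsed versions of the
published survey tables (gene presence for 36 taxa; intergenic characters
for 14).  The printed composite cells concatenate length, inversion mark,
ORF count and match classes ambiguously, so the transcription was done
once, by hand, with the parse rules documented in the fixture loader; a
parser for the printed layout is intentionally not implemented.  One
ambiguous cell (character 0 of *Periconia macrospinosa*) is resolved as
length 913, inverted, four matched ORFs.  Class-level labels
("Leotiomycetes") and the plant order ("Fagales") share the order-label
field with true fungal orders; the distinct-order count simply counts
labels, which is how the survey arrives at 11 fungal orders after
excluding the plant taxon.

## ORF scanning

Intergenic ORFs are defined as an in-frame ATG followed by the first
in-frame stop, entirely inside the span, scanned on both strands; per
(strand, frame, stop) only the longest ORF is reported, and codons
containing N never match a start or stop (a conservative choice for
ambiguous assemblies).  The detection floor defaults to 25 aa, mirroring
common ORF-finder defaults, while the 30-aa threshold — below which
intergenic ORFs tend to show database matches — is exposed as the
short-ORF reporting cutoff rather than the detection floor: the detection
setting behind the published per-region ORF counts is not stated, so the
fixture counts are carried as data and raw-sequence counts are not
promised to reproduce them.  Database matching of ORFs is out of scope;
match classes (fungal/bacterial/amoebal) travel through the fixture as
annotations only.

## Fitch parsimony and tree search

Characters are binary here, though the engine accepts up to 32 states as
bitmask state sets.  Per-character tree length is computed by the Fitch
state-set recursion (missing cells contribute the full state set at the
tip); the score is invariant to rooting, and the compiled kernel accepts
edge matrices in any order, finding the root and a postorder itself.
Duplicate character patterns are compressed into weights before search.

Three search strategies are provided:

* `exhaustive` — stepwise-addition enumeration of all (2n−5)!! unrooted
  topologies, n ≤ 9.
* `branch_and_bound` — the same enumeration pruned with the incumbent
  score; since a partial tree's length never decreases as taxa are added,
  the retained optimal set is provably identical to the exhaustive one,
  n ≤ 12.
* `hill_climb_nni` — seeded random-addition starting trees (greedy
  insertion at the best edge, ties broken at random) refined by
  nearest-neighbour interchange until no move improves the score; best
  trees pooled over replicates and deduplicated by split set.

All equally parsimonious trees are retained up to `max_trees` (default
100), with a strict consensus reported when there are several — for 13
binary characters on 14 taxa many MP trees typically exist, and no
tie-breaking rule can single one out meaningfully.  For the same reason
the package asserts score-level and unique-change properties of the
14-taxon analysis rather than one specific topology.  The default seed
(42) is recorded in the result and in every output header.  A character
whose minimum change count on the tree is exactly one is flagged unique
(single origin); larger counts indicate homoplasy.  Robinson–Foulds
distance (symmetric difference of non-trivial bipartitions) is used for
all tree comparisons.

The heuristic is validated against the exact searches: on random 8-taxon
binary matrices, 10 replicates of NNI hill climbing reach the
branch-and-bound optimum in well over 95% of cases, and per-character
Fitch lengths are checked exhaustively against a brute-force
internal-assignment oracle and against an independent parsimony
implementation.

## The simulator

`sim_params()` fixes the study conditions for all simulation-based
validation: 8 taxa by default on a Yule tree (unit birth rate), loss and
adjacent-pair inversion at 0.3 events per unit branch length,
transposition off by default, intergenic gaps log-normal with median
800 nt and sigma 0.6 (chosen to approximate the observed 500–2000 nt
spread — a modelling choice, not an empirical claim), and planted
intergenic ORFs at 1 per kb with lengths uniform on 10–60 aa.  Event
rates for cluster rearrangement are not quantified anywhere in the
literature we model; the defaults are illustrative and documented as
such.  `swnK` is unlosable so every simulated taxon satisfies the
pipeline's inclusion criterion.

Two deliberate artificialities make the outputs exactly checkable: gene
bodies are random stop-free codons with no codon-usage realism, and
intergenic filler is T-free, so it can contain no start or stop codon on
either strand and every detected intergenic ORF is a planted one.
Sequence-level evolution (substitutions, indels) and horizontal transfer
between lineages are not simulated.  Consequently, passing the
simulator-based tests establishes that the pipeline recovers exactly the
architecture implied by the event log — it does not establish robustness
to annotation error, assembly fragmentation, or sequence divergence in
real data.

Every event, including each leaf's gap draw, is recorded in an event log;
`replay_event_log()` re-derives all leaf layouts deterministically from
the log and must agree byte-for-byte with the simulated layouts.  The
recovery experiment derives the character matrix from simulated leaves,
searches for MP trees (exhaustively for ≤ 9 taxa) and reports the
fraction of replicates whose true topology is among the MP trees, flagging
replicates with no parsimony-informative character as uninformative
rather than counting them either way.

## Degenerate inputs and edge cases

Single-gene layouts yield no adjacencies; empty annotation files yield an
empty result with a warning; records with start > end or start < 1 are
dropped into a report rather than aborting the run, while a duplicated SWN
gene within one taxon/contig aborts with the taxon and gene named.
Overlapping adjacencies carry a flag, length zero and an empty intergenic
sequence.  Newick round-trips keep branch lengths to six significant
digits; NEXUS output quotes labels containing whitespace.

## Problem sizes

The shipped validation uses 200 random 8-taxon matrices for the
heuristic-vs-exact comparison, 100 seeded replicates for the
planted-inversion and replay checks, 50 random 10-kb sequences for the
ORF-scanner equivalence, and 1000 random 14-taxon topologies as the
baseline the MP score must beat.  These sizes give stable pass/fail
behaviour at interactive runtimes; all are plain parameters in the tests
and can be raised.

## Known limitations

* The orientation convention (anchor-gene polarity) is this package's
  choice; analyses that fixed polarity differently (e.g. against a single
  reference genome) will agree on character presence but may disagree on
  which orientation is called A versus B for taxa lacking the anchor.
* Raw-sequence ORF counts depend on the detection floor and are not
  comparable to the curated counts without knowing the original setting.
* The parsimony engine operates on discrete character matrices only; it
  does not align sequences or estimate branch lengths, and bootstrap
  support for alignment-based trees is out of scope.
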