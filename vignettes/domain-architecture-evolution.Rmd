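---
title: "Methods: comparative domain-architecture evolution with domarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative domain-architecture evolution with domarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domarch)
```

## The analysis model

`domarch` treats a protein as its **domain arrangement**: the ordered,
N- to C-terminal list of Pfam domain names. This is the unit of
comparison throughout. The package chains five stages:

1. **Isoform reduction.** Proteome archives ship many isoforms per gene;
   comparative work wants one representative. We group records by the
   gene id parsed from the FASTA header (per-archive regexes, see below)
   and keep the longest sequence. Equal lengths are broken by the
   lexicographically smallest protein id so the choice is reproducible.
   Headers without a recognizable gene tag fall back to treating the
   protein as its own gene — the conservative choice, since wrongly
   merging two genes discards a protein while wrongly splitting one only
   duplicates a row.

2. **Arrangement assembly.** PfamScan hits are filtered by E-value
   (default `evalue_max = 1.0`, i.e. effectively no extra cutoff beyond
   Pfam's own gathering thresholds, which are assumed applied upstream;
   hits flagged insignificant are kept by default and can be dropped with
   a flag), sorted by alignment start, and de-overlapped. Overlap
   resolution is greedy in priority order: lower E-value wins, ties go to
   the higher bit score, then to the earlier start, then to the
   lexicographically smaller domain name — a total order, so assembly is
   invariant to input row order. Domain symbols are Pfam names verbatim;
   `EGF` and `EGF_CA` are distinct and clans are never collapsed
   implicitly.

3. **Arrangement comparison.** Distance between arrangements is unit-cost
   Levenshtein distance over the symbol strings — a true metric, checked
   property-style against an independent implementation.
   `classify_difference()` maps a minimal edit script onto the event
   vocabulary of modular protein evolution with an explicit rubric, in
   precedence order: equal strings → `identical`; no shared symbol →
   `unrelated`; identical run symbols with different run lengths →
   `repeat_count_change`; one contiguous block of pure insertions or
   deletions at a terminus → `terminal_gain_*` / `terminal_loss_*`;
   such a block strictly inside → `internal_insertion` /
   `internal_deletion`; anything else → `complex`. The event names are
   standard; the rubric (e.g. testing repeat changes before terminal
   events, so `A A | A` reads as a repeat contraction rather than a
   terminal loss) is this package's own formalization, since the
   literature names the events but not decision rules.

4. **Homology.** Pairwise scores are optimal Smith–Waterman local
   alignments with affine gaps (a gap of length L costs
   `gap_open + L * gap_extend`; the empty alignment scores 0, so scores
   are non-negative). E-values use the ungapped Karlin–Altschul form
   `K·m·n·exp(−λ·score)` with fixed published constants per matrix
   (BLOSUM62: λ = 0.3176, K = 0.134). These e-values order hits
   sensibly across different sequence lengths; they are *not* claimed to
   reproduce BLAST statistics, and nothing downstream depends on their
   absolute values — only on the induced ranking. Rankings sort by
   ascending e-value, ties by descending score, then lexicographic
   target id, making every downstream decision deterministic.

   Two reciprocity rules are provided. `rbh_orthologs()` is classic
   strict reciprocal-best-hit: both sequences must be each other's
   positional rank-1 hit, which guarantees each protein joins at most one
   pair and the result is symmetric in its arguments.
   `reciprocal_good_hits()` is the relaxed rule used for tracing domain
   origins across large evolutionary distances, where strict RBH rarely
   succeeds: the query's best forward hit is accepted if the query ranks
   within the first `k` (default 3) hits of the reverse search. Reverse
   hits tied with the hit at rank `k` count as within `k` (inclusive),
   because a tie carries no evidence for either ordering. By default only
   the rank-1 forward hit is tested (`forward_depth = 1`), mirroring a
   single search whose top hit is checked reciprocally; widening
   `forward_depth` reproduces "best three forward hits" style searches.
   Exact self-hits (same id) are excluded when a query is ranked against
   its own database, but not across two different sets — a sequence
   present in both sets is always its own good hit.

5. **Evidence integration and Dollo mapping.** For a (gene, species) pair
   the package combines three evidence lines. *Synteny*: the nearest
   neighbours of the gene on its reference scaffold are mapped into the
   target via the ortholog map; both flanks on one scaffold with 1 to
   `gap_genes` (default 3) genes between them means the locus is
   conserved with a candidate in place, direct adjacency means the locus
   survives but the gene is gone, different scaffolds mean the
   neighbourhood itself broke up. Flanks on one scaffold but further than
   `gap_genes` apart are also reported as `flanks_split` — order alone no
   longer supports a conserved locus. The classification uses gene order
   only, so it is invariant to scaffold reversal. *Pseudogene scan*: the
   genomic region is translated in the three forward frames, each
   translation locally aligned to the protein with stop codons scored as
   strong mismatches (the `*` row of the BLOSUM matrices, −4), the best
   frame kept; reported are the aligned fraction of the protein and the
   number of stops inside the aligned span. *Decision table*
   (`call_gene_status()`): an ortholog plus a clean (or absent) scan is
   `present`; an ortholog plus ≥ `stops_min` (default 1) stops over
   ≥ `cov_min` (default 0.5) of the protein is `pseudogene`; no ortholog
   plus a broken or emptied neighbourhood plus at most weak genomic
   alignment is `lost`; everything else is `ambiguous`. An optional
   `clade_hit` input — a match found elsewhere in the surrounding clade —
   downgrades `lost` to `ambiguous`, representing the case where absence
   from one assembly is not decisive.

   Presence matrices (`+`/`-`/`?`) are mapped per protein onto a rooted
   species tree under **Dollo parsimony**: a single gain with any number
   of subsequent losses. The gain is placed on the *stem branch above*
   the most recent common ancestor of all present leaves, so statements
   like "before the divergence of X" map directly to branch names. The
   loss set consists of the maximal subtrees inside the gain clade that
   contain no present leaf but at least one absent leaf; this is the
   provably minimal set (each such subtree needs one loss and no loss can
   cover two of them, since their common ancestor governs a present
   leaf), and tests verify minimality exhaustively against brute-force
   enumeration on small trees. Unknown (`?`) leaves impose no constraint
   and inherit the state of the branch governing them; tips absent from
   the matrix count as unknown. Dollo is the right model here because
   the biology being represented reasons this way — single emergences
   followed by independent lineage losses; independent-gain scenarios are
   out of scope.

## Header dialects

Gene ids are extracted with one capture group per dialect:
Ensembl `gene[:= ]\s*(\S+)`, UniProt `GN[:= ]\s*(\S+)`, NCBI
`\[gene=...\]` bracket tags. The regex is part of the dialect object
rather than hard-coded, so archive-specific variants are configuration,
not code changes.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `evalue_max` | 1.0 | arrangement hit filter (Pfam gathering thresholds assumed upstream) |
| matrix, `gap_open`, `gap_extend` | BLOSUM62, 11, 1 | standard protein search configuration; a configuration choice, not a claim |
| `k` | 3 | reverse-search depth of relaxed reciprocity |
| `forward_depth` | 1 | forward hits tested per query |
| `cov_min` | 0.5 | minimum aligned protein fraction for a scan to count as covering |
| `stops_min` | 1 | premature stops needed to call a pseudogene |
| `gap_genes` | 3 | max intervening genes for flanks to count as adjacent |

`cov_min`, `stops_min` and `gap_genes` are explicit stand-ins for
qualitative published criteria ("bad hit", "no synteny"); they are
documented configuration, not reconstructions of unstated cutoffs.

## The synthetic-data generator

`simulate_dataset()` evolves a root gene repertoire along a tree with
branch lengths. Each root gene is a list of domain instances; every
domain family has a fixed pseudo-random prototype sequence, and each root
gene's instances diverge ~10% from the prototype (deterministically keyed
by gene and position), so families are separable even when their domain
compositions overlap, while two instances of one family remain clearly
homologous. Proteins are concatenations of domain sequences with a short
`GS` linker, which lets domain databases be sliced exactly; real domain
boundary fuzziness is not modelled.

Events — duplication, gene loss, terminal domain loss/gain,
fusion/fission, repeat-count change, pseudogenization — occur with
exponential (Gillespie-style) waiting times at per-gene rates per unit
branch length. The intensity on a branch is fixed by the repertoire size
at the branch start, so per-branch event counts are Poisson with mean
(rate × n₀ × length), which the tests verify across replicates. Each
branch has its own RNG stream keyed by (seed, branch), so any branch
replays identically and whole datasets are byte-identical under a fixed
seed. Substitutions are applied per site with probability
rate × branch length, uniformly over the other 19 residues.
Pseudogenization back-translates the protein (fixed codon table: the most
frequent human codon per residue) and plants 1–5 in-frame `TAA` codons,
logged exactly; stops are spread over the middle 10–90% of the sequence
because stops hard against the ends would be trimmed off by any local
alignment. Genomic copies are intron-free back-translations — the
pseudogene scan is therefore exact on its own data, and spliced real
genes are explicitly out of scope.

The default configuration — four species on a balanced tree with 0.05
branch lengths, eight root genes of 2–5 domains, event rates 0.01–0.05
per gene per unit length, substitution rate 0.05, two isoforms per gene,
one species each of the Ensembl/UniProt/NCBI header dialects — describes
a small, moderately diverged vertebrate-like dataset: divergence a few
percent between sister species, roughly one repertoire event expected per
lineage. Passing tests on these data show the machinery is correct on
intron-free, linker-concatenated, uniformly substituted proteins; they do
not show robustness to fragmented assemblies, splice variation or domain
boundary noise in real proteomes.

`coagulation_fixture()` is the complementary hand-authored dataset: the
published coagulation-cascade arrangements, the clade-level presence
matrix (including the unknown state for FV in jawless vertebrates), the
vertebrate clade topology with named internal nodes, a cetacean FXII
genomic copy carrying four in-frame stops, and a split-scaffold
ccdc80/gpr161 neighbourhood in jawless vertebrates. Its sequences are
synthetic constructions consistent with those published facts; file and
object documentation say so explicitly.

## Numerical and degenerate-input choices

* Empty hit lists produce empty arrangements; empty inputs to isoform
  cleaning pass through; an all-absent protein maps to "no gain, zero
  losses" rather than an error.
* Sequences are sanitized on ingest: `*` stripped with a warning,
  letters outside the 20 standard residues mapped to `X`.
* All ranking and overlap tie-breaks end in a lexicographic comparison,
  so every code path is a total order and the pipeline is deterministic;
  the end-to-end determinism of `run_pipeline()` is asserted
  byte-for-byte in the tests, with the only timestamp confined to the
  run manifest.
* The pipeline's presence matrix is restricted to species on the tree;
  species present in the dataset but not on the tree (outgroups) are
  used for homology only.

## Problem sizes used in the test-suite

Oracle-equivalence checks run Smith–Waterman against brute-force dynamic
programming on 50 random pairs of length ≤ 12; relaxed reciprocity
against exhaustive enumeration on 100 random 5×5–8×8 score matrices with
k ∈ {1,2,3}; and Dollo loss counts against exhaustive single-gain
enumeration on 50 random trees with ≤ 8 leaves. Parameter-recovery runs
use the default four-species generator. These sizes were chosen so the
oracles stay exhaustive (the point of an oracle) while the suite stays
quick to iterate on.

## Known limitations

* The pseudogene scan models a single forward frame without introns or
  frameshifts (`frameshift_breaks` is always 0); reverse-strand regions
  must be reverse-complemented upstream.
* E-values are ungapped Karlin–Altschul approximations; use the
  `score_fun` adapter to inject scores from a real search engine where
  BLAST-exact statistics matter.
* The difference classifier explains one pairwise comparison; it does not
  reconstruct multi-event histories (a combined terminal gain *and* loss
  reads as `complex`).
* Dollo mapping reports one minimal scenario; when several loss
  placements tie (possible only through unknown-state leaves), the
  reported set is the maximal-subtree one described above.
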