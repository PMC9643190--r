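# domarch — comparative evolution of protein domain architectures

`domarch` is an R package for tracing how multi-domain proteins arise,
change and disappear across a phylogeny, built around the vertebrate blood
coagulation cascade as its model system. It is aimed at molecular
evolution researchers who want a self-contained, testable version of the
classic comparative workflow: reduce proteomes to longest isoforms, read
Pfam domain annotations, compare ordered **domain arrangements** (the N- to
C-terminal list of Pfam domains on a protein, e.g. factor IX's
`Gla – EGF – FXa_inhibition – Trypsin`), infer homology with reciprocal
local-alignment searches, weigh ortholog / synteny / pseudogene evidence
for "missing" genes, and map protein gains and losses onto a species tree.

## What it computes

* **Ingest** — proteome FASTA in Ensembl / UniProt / NCBI header dialects
  (gene tags extracted with configurable regexes such as
  `gene[:= ]\s*(\S+)`), longest-isoform reduction with deterministic
  tie-breaking, and a parser/writer for PfamScan tabular output.
* **Arrangements** — assembly of domain hits into arrangements
  (E-value filter, overlap resolution by E-value → bit score → position),
  Levenshtein edit distance between arrangements, classification of
  differences into the modular-evolution event vocabulary (terminal
  gain/loss, internal insertion/deletion, repeat-count change, …), and
  run-length repeat profiles.
* **Homology** — Smith–Waterman local alignment (affine gaps, BLOSUM
  matrices) with Karlin–Altschul e-values, hit ranking, classic
  reciprocal-best-hit orthologs, and the *relaxed top-k reciprocity* rule:
  a forward hit is accepted when the query ranks within the first `k`
  (default 3) hits of the reverse search — the rule used to trace domain
  origins across distant clades.
* **Evidence** — for a gene missing from a proteome: flanking-gene synteny
  (is the neighbourhood intact, split across scaffolds, or gone?), a
  protein-to-genome scan that counts in-frame premature stop codons, and a
  total decision table resolving `present` / `lost` / `pseudogene` /
  `ambiguous`.
* **Dollo parsimony** — single-gain, minimal-loss mapping of a `+`/`-`/`?`
  presence matrix onto a rooted Newick tree, with provably minimal loss
  sets and branch-labelled reports.
* **Synthetic data** — a seeded simulator that evolves a gene repertoire
  along a tree (duplication, loss, terminal domain gain/loss,
  fusion/fission, repeat changes, pseudogenization by in-frame stops,
  substitutions) and emits the same file formats plus a ground-truth log,
  so every stage is testable without downloads. A hand-authored fixture
  encodes the published coagulation-cascade biology (arrangements,
  clade-level presence matrix, a pseudogenized cetacean FXII, the
  split-scaffold FV neighbourhood in jawless vertebrates).

## Worked example

```r
library(domarch)

fx <- coagulation_fixture(file.path(tempdir(), "coag"))

# Factor XI: four tandem apple domains before the protease domain
fx$arrangements$XI
#> <domain_arrangement> XI: PAN_1 – PAN_1 – PAN_1 – PAN_1 – Trypsin
repeat_profile(fx$arrangements$XI)
#> <repeat_profile> PAN_1 ×4; Trypsin ×1

# FX vs FVII differ by an internal loss of the FXa-inhibition domain
classify_difference(fx$arrangements$X, fx$arrangements$VII)
#> <arrangement_diff> internal_deletion (edit distance 1)
#>   position    domain_name  op
#> 3        3 FXa_inhibition del

# Dollo mapping of factor XII on the vertebrate clade tree:
# one gain on the tetrapod stem, independent losses in birds and cetaceans
dollo_map(fx$presence, fx$tree, "XII")
#> <gain_loss> XII: gain on 'tetrapoda', 2 loss(es) [bird, cetacean]

# The cetacean genomic copy of FXII is a pseudogene: the scan finds four
# in-frame nonsense mutations over the full protein span
prot <- clean_isoforms(read_proteome(
  file.path(tempdir(), "coag", "placental.proteome.fa"),
  "ensembl", "placental"))
gen <- Biostrings::readDNAStringSet(
  file.path(tempdir(), "coag", "cetacean.genomic.fa"))
pseudogene_scan(prot$sequence[prot$gene_id == "XII"],
                as.character(gen[["GENE_XII"]]))
#> <pseudogene_scan> frame 1, aligned fraction 1.00, 4 premature stop(s)
```

The numbers read as: the FXI arrangement carries a `PAN_1` run of length 4;
the FX→FVII difference is a single internal domain deletion; under Dollo
parsimony FXII needs exactly one origin (on the branch below the tetrapod
ancestor) and two losses; and the planted cetacean pseudogene is recovered
with its four premature stops at full protein coverage, which the evidence
table resolves to status `pseudogene`.

A thin command-line front end over the same functions ships at
`inst/cli/domarch.R` (subcommands `simulate`, `fixture`, `ingest`,
`arrangements`, `homology`, `dollo`, `run-all`).

## Scope notes

The package consumes PfamScan-style annotations; it does not run HMMER or
download Pfam. The internal Smith–Waterman search is a desk-scale
stand-in for BLASTP with an adapter (`score_fun`) for plugging in external
tabular search results. The pseudogene scan models intron-free,
forward-strand coding regions — see the methods vignette
(`vignettes/domain-architecture-evolution.Rmd`) for assumptions,
parameter defaults and limitations.
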