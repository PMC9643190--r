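mk_order <- function(species, scaffolds, genes) {
  n <- length(genes)
  data.frame(species = species, scaffold = scaffolds, gene_id = genes,
             start = seq(1L, by = 10000L, length.out = n),
             end = seq(5000L, by = 10000L, length.out = n),
             strand = rep("+", n), stringsAsFactors = FALSE)
}

ref_order <- mk_order("ref", "chr1", c("ccdc80", "FV", "gpr161", "x1"))
omap <- c(ccdc80 = "ccdc80_t", gpr161 = "gpr161_t", x1 = "x1_t")

test_that("synteny check classifies the flanking-gene neighbourhood", {
  # conserved: candidate between the flank orthologs
  tgt <- mk_order("t", "s1", c("ccdc80_t", "cand", "gpr161_t"))
  r <- synteny_check(ref_order, tgt, "FV", omap)
  expect_equal(r$state, "conserved_with_candidate")
  expect_equal(r$left_flank, "ccdc80")
  expect_equal(r$right_flank, "gpr161")
  # locus present, gene missing: flanks adjacent
  tgt2 <- mk_order("t", "s1", c("ccdc80_t", "gpr161_t"))
  expect_equal(synteny_check(ref_order, tgt2, "FV", omap)$state,
               "locus_present_gene_missing")
  # flank orthologs on different scaffolds
  tgt3 <- mk_order("t", c("s1", "s2"), c("ccdc80_t", "gpr161_t"))
  expect_equal(synteny_check(ref_order, tgt3, "FV", omap)$state,
               "flanks_split")
  # unmapped flank
  expect_equal(synteny_check(ref_order, tgt, "FV",
                             omap[names(omap) != "gpr161"])$state,
               "flanks_missing")
  # flanks further apart than gap_genes
  tgt4 <- mk_order("t", "s1", c("ccdc80_t", paste0("f", 1:5), "gpr161_t"))
  expect_equal(synteny_check(ref_order, tgt4, "FV", omap,
                             gap_genes = 3L)$state, "flanks_split")
  expect_equal(synteny_check(ref_order, tgt4, "FV", omap,
                             gap_genes = 6L)$state,
               "conserved_with_candidate")
  expect_error(synteny_check(ref_order, tgt, "nope", omap), "not present")
})

test_that("synteny is invariant to reversing the target scaffold", {
  tgt <- mk_order("t", "s1", c("ccdc80_t", "cand", "gpr161_t"))
  rev_tgt <- tgt[rev(seq_len(nrow(tgt))), ]
  rev_tgt$start <- seq(1L, by = 10000L, length.out = nrow(tgt))
  rev_tgt$end <- rev_tgt$start + 4999L
  rev_tgt$strand <- "-"
  expect_equal(synteny_check(ref_order, rev_tgt, "FV", omap)$state,
               synteny_check(ref_order, tgt, "FV", omap)$state)
})

test_that("clean back-translations scan with zero premature stops (property)", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_aa(sample(40:120, 1))
    sc <- pseudogene_scan(p, back_translate(p))
    expect_equal(sc$premature_stops, 0L)
    expect_gte(sc$aligned_fraction, 0.99)
  }
})

test_that("n inserted in-frame stops are recovered exactly for n <= 10", {
  set.seed(42)
  p <- random_aa(250)
  dna <- back_translate(p)
  for (n in 1:10) {
    mut <- insert_stop_codons(dna, n)
    expect_length(mut$codon_positions, n)
    sc <- pseudogene_scan(p, mut$dna)
    expect_equal(sc$premature_stops, n)
    expect_gte(sc$aligned_fraction, 0.9)
  }
})

test_that("unrelated DNA aligns to below the coverage threshold", {
  set.seed(43)
  p <- random_aa(300)
  for (i in 1:5) {
    dna <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
    sc <- pseudogene_scan(p, dna)
    expect_lt(sc$aligned_fraction, 0.2)
  }
  expect_error(pseudogene_scan(p, "ACGU"), "ACGTN")
  expect_error(pseudogene_scan(p, "AC"), "codon")
})

test_that("gene status decision table is total and matches the documented rules", {
  scan_clean <- pseudogene_scan(random_aa(60), back_translate(random_aa(60)))
  scan_pseudo <- list(aligned_fraction = 0.95, premature_stops = 4L,
                      frameshift_breaks = 0L)
  class(scan_pseudo) <- "pseudogene_scan"
  scan_weak <- list(aligned_fraction = 0.15, premature_stops = 2L,
                    frameshift_breaks = 0L)
  class(scan_weak) <- "pseudogene_scan"
  syn <- function(state) structure(list(state = state, left_flank = "l",
                                        right_flank = "r", details = ""),
                                   class = "synteny_result")
  # pseudogenized FXII-like case: ortholog present, high-coverage scan with
  # premature stops
  expect_equal(call_gene_status(TRUE, NULL, scan_pseudo), "pseudogene")
  # ortholog with no scan, or a clean scan -> present
  expect_equal(call_gene_status(TRUE, NULL, NULL), "present")
  expect_equal(call_gene_status(TRUE, syn("flanks_split"), NULL), "present")
  # FV-in-jawless-like case: no ortholog, split flanks, weak fragments
  expect_equal(call_gene_status(FALSE, syn("flanks_split"), scan_weak),
               "lost")
  expect_equal(call_gene_status(FALSE, syn("locus_present_gene_missing"),
                                NULL), "lost")
  # a clade-wide hit downgrades lost to ambiguous
  expect_equal(call_gene_status(FALSE, syn("flanks_split"), scan_weak,
                                clade_hit = TRUE), "ambiguous")
  # exhaustive: every combination resolves to exactly one valid status
  scans <- list(NULL, scan_clean, scan_pseudo, scan_weak)
  states <- c(NA, "conserved_with_candidate", "locus_present_gene_missing",
              "flanks_split", "flanks_missing")
  for (of in c(TRUE, FALSE)) for (st in states) for (sc in scans)
    for (ch in c(TRUE, FALSE)) {
      s <- if (is.na(st)) NULL else syn(st)
      out <- call_gene_status(of, s, sc, clade_hit = ch)
      expect_true(out %in% c("present", "lost", "ambiguous", "pseudogene"))
      expect_length(out, 1L)
    }
  # stops below coverage threshold stay ambiguous rather than pseudogene
  expect_equal(call_gene_status(TRUE, NULL, scan_weak), "ambiguous")
})

test_that("evidence bundles carry their resolved status", {
  b <- evidence_bundle("FXII", "cetacean", TRUE, NULL,
                       structure(list(aligned_fraction = 0.99,
                                      premature_stops = 4L,
                                      frameshift_breaks = 0L),
                                 class = "pseudogene_scan"))
  expect_equal(b$status, "pseudogene")
})

test_that("gene-order tables round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_gene_order(ref_order, tmp)
  expect_equal(read_gene_order(tmp), ref_order)
})
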