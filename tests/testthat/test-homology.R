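test_that("self-alignment scores the diagonal sum; disjoint sequences floor at 0", {
  s <- "MKVLWAALLV"
  res <- local_align_score(s, s)
  diag_sum <- sum(vapply(strsplit(s, "")[[1]],
                         function(ch) blosum62[ch, ch], 0))
  expect_equal(unname(res["score"]), diag_sum)
  expect_equal(unname(local_align_score("AAAA", "CCCC")["score"]), 0)
  expect_error(local_align_score("", "A"), "non-empty")
  expect_error(local_align_score("A", "A", align_params("NOSUCH")), "unknown")
})

test_that("alignment scores are symmetric and e-values rank by score", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
    ra <- local_align_score(a, b); rb <- local_align_score(b, a)
    expect_equal(ra["score"], rb["score"])
    expect_equal(ra["e_value"], rb["e_value"])
  }
  # same lengths: higher score <=> lower e-value
  a <- random_aa(20)
  r1 <- local_align_score(a, a)
  r2 <- local_align_score(a, random_aa(20))
  expect_gt(unname(r1["score"]), unname(r2["score"]))
  expect_lt(unname(r1["e_value"]), unname(r2["e_value"]))
})

test_that("hit ranking orders by e-value with deterministic ties", {
  db <- rbind(seq_entry("t1", "MKVLWAALLV"),
              seq_entry("t2", "MKVLWAALLV"),
              seq_entry("t3", "PPPPGGGG"))
  q <- seq_entry("q", "MKVLWAALLV")
  r <- rank_hits(q, db)
  expect_s3_class(r, "hit_ranking")
  # identical targets tie on e-value and score -> lexicographic ids
  expect_equal(r$hits$target_id, c("t1", "t2", "t3"))
  # singleton database
  r1 <- rank_hits(q, db[1, ])
  expect_equal(r1$hits$target_id, "t1")
  # exact copy of the query ranks first among unrelated sequences
  db2 <- rbind(seq_entry("x", "WWWHHHKKK"), seq_entry("copy", "MKVLWAALLV"),
               seq_entry("y", "GGGGAAAA"))
  expect_equal(rank_hits(q, db2)$hits$target_id[1], "copy")
  # self-exclusion by id
  db3 <- rbind(seq_entry("q", "MKVLWAALLV"), seq_entry("z", "MKVL"))
  expect_false("q" %in% rank_hits(q, db3)$hits$target_id)
  expect_error(rank_hits(q, db3[db3$id == "q", ]), "empty database")
})

test_that("relaxed top-k reciprocity matches exhaustive enumeration and is monotone in k", {
  set.seed(31)
  for (rep in 1:30) {
    nA <- sample(5:8, 1); nB <- sample(5:8, 1)
    S <- matrix(sample(0:40, nA * nB, TRUE), nA, nB)
    ms <- matrix_sets(S)
    prev <- NULL
    for (k in 1:3) {
      gh <- reciprocal_good_hits(ms$setA, ms$setB, k = k,
                                 score_fun = ms$scorer)
      got <- if (nrow(gh)) paste(gh$query_id, gh$target_id) else character(0)
      orc <- good_hits_oracle(S, k)
      want <- if (nrow(orc)) paste(sprintf("a%02d", orc[, "q"]),
                                   sprintf("b%02d", orc[, "t"])) else
        character(0)
      expect_setequal(got, want)
      if (!is.null(prev)) expect_true(all(prev %in% got))
      prev <- got
    }
  }
})

test_that("a reverse hit at rank 3 passes k=3 but not k=1", {
  # q's best forward hit is t; in t's reverse ranking q is 3rd
  S <- matrix(0, 3, 1, dimnames = NULL)
  S[1, 1] <- 10   # q = a01
  S[2, 1] <- 30
  S[3, 1] <- 20
  ms <- matrix_sets(S)
  g3 <- reciprocal_good_hits(ms$setA, ms$setB, k = 3, score_fun = ms$scorer)
  row <- g3[g3$query_id == "a01", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$reverse_rank, 3L)
  g1 <- reciprocal_good_hits(ms$setA, ms$setB, k = 1, score_fun = ms$scorer)
  expect_false("a01" %in% g1$query_id)
})

test_that("mutual best hits pair with ranks (1,1) and self-hits dominate", {
  a <- rbind(seq_entry("pa", "MKVLWAALLVMKVLWAALLV"))
  b <- rbind(seq_entry("pb", "MKVLWAALLVMKVLWAGLLV"))
  gh <- reciprocal_good_hits(a, b, k = 3)
  expect_equal(gh$forward_rank, 1L)
  expect_equal(gh$reverse_rank, 1L)
  # a sequence present in both sets is a good hit with itself at any k
  shared <- seq_entry("same", "MKVLWAALLVHHHH")
  setA <- rbind(shared, seq_entry("o1", "GGGGAAAAGGGG"))
  setB <- rbind(shared, seq_entry("o2", "PPPPWWWWPPPP"))
  for (k in 1:3) {
    gh <- reciprocal_good_hits(setA, setB, k = k)
    expect_true(any(gh$query_id == "same" & gh$target_id == "same"))
  }
})

test_that("strict RBH orthologs are symmetric, unique and recover identical proteomes", {
  mk <- function(prefix, seqs) do.call(rbind, lapply(seq_along(seqs),
    function(i) seq_entry(paste0(prefix, i), seqs[i])))
  seqs <- c("MKVLWAALLVAGCQ", "PPPPGGGGWWHH", "TTTTRRRRDDEE")
  A <- mk("a", seqs); B <- mk("b", seqs)
  p <- rbh_orthologs(A, B)
  expect_equal(nrow(p), 3L)
  expect_equal(sub("a", "", p$query_id), sub("b", "", p$target_id))
  # symmetry under swapping the proteomes
  q <- rbh_orthologs(B, A)
  expect_setequal(paste(p$query_id, p$target_id),
                  paste(q$target_id, q$query_id))
  # duplicated gene: at most one copy pairs
  Adup <- rbind(A, seq_entry("a1dup", seqs[1]))
  pd <- rbh_orthologs(Adup, B)
  expect_lte(sum(pd$target_id == "b1"), 1L)
  expect_lte(max(table(pd$query_id)), 1L)
})

test_that("hit tables round-trip through the tabular format", {
  hits <- data.frame(query_id = c("q1", "q2"), target_id = c("t1", "t2"),
                     score = c(55.5, 12), e_value = c(1.5e-12, 0.22),
                     stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, tmp)
  expect_equal(read_hit_table(tmp), hits)
})
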