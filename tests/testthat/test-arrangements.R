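mk_hits <- function(protein_id, doms, starts, ends, evalues = NULL,
                    bits = NULL) {
  n <- length(doms)
  data.frame(protein_id = protein_id, ali_start = starts, ali_end = ends,
             env_start = starts, env_end = ends, hmm_acc = "PF00000.1",
             domain_name = doms, type = "Domain", hmm_start = 1L,
             hmm_end = ends - starts + 1L, hmm_length = ends - starts + 1L,
             bit_score = bits %||% rep(50, n),
             e_value = evalues %||% rep(1e-10, n),
             significance = 1L, clan = "", significant = TRUE,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("arrangements assemble from hits in N-to-C order", {
  h <- mk_hits("FIX", c("Trypsin", "Gla", "EGF", "FXa_inhibition"),
               starts = c(140L, 1L, 50L, 90L), ends = c(380L, 45L, 85L, 130L))
  a <- build_arrangement(h)
  expect_s3_class(a, "domain_arrangement")
  expect_equal(a$domains, c("Gla", "EGF", "FXa_inhibition", "Trypsin"))
  # invariant to input hit order
  for (perm in 1:5) {
    hp <- h[sample(nrow(h)), ]
    expect_equal(build_arrangement(hp)$domains, a$domains)
  }
  # empty
  expect_length(build_arrangement(h[0, ])$domains, 0L)
  # mixed proteins rejected
  h2 <- h; h2$protein_id[1] <- "other"
  expect_error(build_arrangement(h2), "multiple proteins")
})

test_that("overlap resolution keeps the better-supported hit", {
  h <- mk_hits("P", c("Kringle", "PAN_1"), starts = c(10L, 30L),
               ends = c(90L, 110L), evalues = c(1e-10, 1e-3))
  a <- build_arrangement(h)
  expect_equal(a$domains, "Kringle")
  # e-value tie -> higher bit score wins
  h2 <- mk_hits("P", c("Kringle", "PAN_1"), starts = c(10L, 30L),
                ends = c(90L, 110L), evalues = c(1e-5, 1e-5),
                bits = c(20, 80))
  expect_equal(build_arrangement(h2)$domains, "PAN_1")
  # e-value filter applies before assembly
  h3 <- mk_hits("P", c("Gla", "EGF"), starts = c(1L, 50L),
                ends = c(45L, 85L), evalues = c(1e-9, 5))
  expect_equal(build_arrangement(h3, evalue_max = 1)$domains, "Gla")
})

test_that("arrangement edit distance matches an independent oracle and is a metric", {
  expect_equal(arrangement_distance(c("Gla", "EGF", "FXa_inhibition",
                                      "Trypsin"),
                                    c("Gla", "EGF", "FXa_inhibition",
                                      "Trypsin")), 0L)
  set.seed(5)
  pool <- c("Gla", "EGF", "Kringle", "PAN_1", "Trypsin", "VWD")
  draw <- function() sample(pool, sample(0:8, 1), replace = TRUE)
  for (i in 1:60) {
    a <- draw(); b <- draw(); c_ <- draw()
    dab <- arrangement_distance(a, b)
    expect_equal(dab, lev_oracle(a, b))
    expect_equal(dab, arrangement_distance(b, a))       # symmetry
    expect_equal(arrangement_distance(a, a), 0L)        # identity
    expect_lte(dab, arrangement_distance(a, c_) +
                    arrangement_distance(c_, b))        # triangle
  }
})

test_that("difference classification reproduces the event vocabulary", {
  fx <- c("Gla", "EGF", "FXa_inhibition", "Trypsin")
  fvii <- c("Gla", "EGF", "Trypsin")
  d <- classify_difference(fx, fvii)
  expect_equal(d$kind, "internal_deletion")
  expect_equal(d$edit_distance, 1L)
  expect_equal(d$details$domain_name, "FXa_inhibition")

  expect_equal(classify_difference(fx, fx)$kind, "identical")
  expect_equal(classify_difference(fx, fx)$edit_distance, 0L)

  fxi <- c(rep("PAN_1", 4), "Trypsin")
  fxi3 <- c(rep("PAN_1", 3), "Trypsin")
  expect_equal(classify_difference(fxi, fxi3)$kind, "repeat_count_change")
  expect_equal(classify_difference(fxi, fxi3)$edit_distance, 1L)

  expect_equal(classify_difference(fvii, c("Kringle", fvii))$kind,
               "terminal_gain_N")
  expect_equal(classify_difference(c("Kringle", fvii), fvii)$kind,
               "terminal_loss_N")
  expect_equal(classify_difference(fvii, fvii[-3])$kind, "terminal_loss_C")
  expect_equal(classify_difference(fvii[-3], fvii)$kind, "terminal_gain_C")
  expect_equal(classify_difference(fvii,
                                   c("Gla", "Sushi", "EGF", "Trypsin"))$kind,
               "internal_insertion")
  expect_equal(classify_difference(c("Gla"), c("VWD", "TIL"))$kind,
               "unrelated")
  # identical <=> equal symbol strings (property)
  set.seed(6)
  pool <- c("Gla", "EGF", "Trypsin")
  for (i in 1:30) {
    a <- sample(pool, sample(1:5, 1), TRUE)
    b <- sample(pool, sample(1:5, 1), TRUE)
    expect_equal(classify_difference(a, b)$kind == "identical",
                 identical(a, b))
  }
})

test_that("repeat profiles run-length encode and round-trip", {
  fxi <- c("PAN_1", "PAN_1", "PAN_1", "PAN_1", "Trypsin")
  pr <- repeat_profile(fxi)
  expect_equal(pr$domain_name, c("PAN_1", "Trypsin"))
  expect_equal(pr$count, c(4L, 1L))
  thrb <- c("Gla", "Kringle", "Kringle", "Thrombin_light", "Trypsin")
  prt <- repeat_profile(thrb)
  expect_equal(prt$count[prt$domain_name == "Kringle"], 2L)
  expect_equal(repeat_profile("Trypsin")$count, 1L)
  set.seed(7)
  for (i in 1:20) {
    a <- sample(c("A", "B", "C"), sample(1:12, 1), TRUE)
    expect_equal(expand_repeat_profile(repeat_profile(a)), a)
    pr <- repeat_profile(a)
    expect_true(all(diff(as.integer(factor(pr$domain_name,
      levels = unique(pr$domain_name)))) != 0 |
      pr$domain_name[-1] != pr$domain_name[-nrow(pr)]))
    expect_equal(sum(pr$count), length(a))
  }
})

test_that("shared domains are the symbol intersection", {
  vwf <- c("VWD", "TIL", "C8", "VWD", "TIL", "C8", "VWA", "VWC")
  hml <- c("VWD", "TIL", "C8", "VWD", "fn2")
  expect_equal(shared_domains(vwf, hml), c("C8", "TIL", "VWD"))
  expect_length(shared_domains(c("Gla"), c("Trypsin")), 0L)
  expect_equal(shared_domains(vwf, vwf), sort(unique(vwf)))
})
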