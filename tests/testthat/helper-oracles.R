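# Independent oracles used to check the package implementations.

aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(aa_alphabet, n, TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Plain affine-gap Smith-Waterman dynamic program (gap of length L costs
# open + L * ext), written independently of the package code path.
sw_oracle <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[, 1] <- 0; M[1, ] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                   Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    best <- max(best, M[i, j])
  }
  best
}

# Levenshtein via utils::adist on single-character encodings of symbols.
lev_oracle <- function(a, b) {
  syms <- unique(c(a, b))
  stopifnot(length(syms) <= 52)
  code <- setNames(c(letters, LETTERS)[seq_along(syms)], syms)
  as.integer(utils::adist(paste(code[a], collapse = ""),
                          paste(code[b], collapse = ""))[1, 1])
}

# Exhaustive single-gain Dollo minimum: enumerate every gain node and every
# subset of candidate loss edges; a scenario is valid when all present
# leaves are reached and no absent leaf is.
dollo_oracle <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    desc[[po$edge[e, 1]]] <- c(desc[[po$edge[e, 1]]], desc[[po$edge[e, 2]]])
  present <- which(states == "+")
  absent <- which(states == "-")
  if (length(present) == 0) return(0L)
  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  path_nodes <- function(leaf, gain) {
    # nodes on the path from leaf up to (and including) gain
    out <- integer(0); n <- leaf
    repeat {
      out <- c(out, n)
      if (n == gain) return(out)
      if (n == root) return(NULL)
      n <- parent_of[n]
    }
  }
  gains <- Filter(function(g) all(present %in% desc[[g]]), seq_len(nnode))
  best <- Inf
  for (g in gains) {
    cand <- Filter(function(n) n != g && n %in% which(
      vapply(desc, function(d) all(d %in% desc[[g]]), TRUE)) &&
        !any(desc[[n]] %in% present), seq_len(nnode))
    if (length(cand) > 14) stop("oracle: too many candidate loss edges")
    found <- FALSE
    for (size in 0:length(cand)) {
      if (size >= best) break
      combos <- if (size == 0) list(integer(0)) else
        utils::combn(cand, size, simplify = FALSE)
      for (loss in combos) {
        ok <- TRUE
        for (lf in present) {
          if (any(path_nodes(lf, g) %in% loss)) { ok <- FALSE; break }
        }
        if (ok) for (lf in absent) {
          pn <- path_nodes(lf, g)
          covered <- is.null(pn) || any(pn %in% loss)
          if (!covered) { ok <- FALSE; break }
        }
        if (ok) { best <- min(best, size); found <- TRUE; break }
      }
      if (found) break
    }
  }
  as.integer(best)
}

# Exhaustive relaxed top-k reciprocity on a score matrix: rank by counting
# strictly better competitors (ties therefore share the better rank, which
# is the package's inclusive tie rule).
good_hits_oracle <- function(S, k, forward_depth = 1) {
  nA <- nrow(S); nB <- ncol(S)
  # higher score = better; e-value taken as -score (monotone)
  fwd_rank <- function(q, t) {
    better <- sum(S[q, ] > S[q, t])
    ties_before <- sum(S[q, ] == S[q, t] &
                         seq_len(nB) < t)
    better + ties_before + 1
  }
  rev_rank_inclusive <- function(t, q) {
    1 + sum(S[, t] > S[q, t])
  }
  out <- list()
  for (q in seq_len(nA)) {
    ord <- order(-S[q, ], seq_len(nB))
    for (r in seq_len(min(forward_depth, nB))) {
      t <- ord[r]
      rr <- rev_rank_inclusive(t, q)
      if (rr <= k)
        out[[length(out) + 1]] <- c(q = q, t = t)
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("q", "t")))
}

# seq_entry sets and matrix-backed scorer for reciprocity tests
matrix_sets <- function(S) {
  nA <- nrow(S); nB <- ncol(S)
  setA <- do.call(rbind, lapply(seq_len(nA), function(i)
    seq_entry(sprintf("a%02d", i), "M")))
  setB <- do.call(rbind, lapply(seq_len(nB), function(j)
    seq_entry(sprintf("b%02d", j), "M")))
  scorer <- function(qrow, trow) {
    i <- as.integer(substring(qrow$id, 2))
    j <- as.integer(substring(trow$id, 2))
    s <- S[i, j]
    c(score = s, e_value = -s)
  }
  list(setA = setA, setB = setB, scorer = scorer)
}
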