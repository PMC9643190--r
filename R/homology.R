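# Published ungapped Karlin–Altschul parameters per substitution matrix.
# Only the ranking induced by the resulting e-values is contractual; the
# constants make scores from sequences of different lengths comparable.
KA_PARAMS <- list(
  BLOSUM62 = c(lambda = 0.3176, K = 0.134),
  BLOSUM45 = c(lambda = 0.2291, K = 0.0924),
  BLOSUM80 = c(lambda = 0.3430, K = 0.1770),
  PAM250   = c(lambda = 0.2290, K = 0.0900)
)

#' Alignment parameters for homology searches
#'
#' @param matrix Substitution matrix name: one of `"BLOSUM62"` (default),
#'   `"BLOSUM45"`, `"BLOSUM80"`, `"PAM250"` (matrices shipped with
#'   Biostrings).
#' @param gap_open,gap_extend Affine gap penalties (positive costs); a gap
#'   of length L costs `gap_open + L * gap_extend`. Defaults 11 / 1.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (!matrix %in% names(KA_PARAMS))
    stopf("unknown substitution matrix '%s' (have: %s)", matrix,
          paste(names(KA_PARAMS), collapse = ", "))
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Smith–Waterman local alignment score and e-value
#'
#' Optimal local alignment score under affine gap costs, with the empty
#' alignment scoring 0 (so the score is never negative). The e-value is the
#' ungapped Karlin–Altschul approximation `K * m * n * exp(-lambda * score)`
#' with fixed published constants per matrix; it orders hits sensibly but is
#' not a BLAST-exact statistic.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param params An [align_params()].
#' @return Named numeric vector `c(score =, e_value =)`.
#' @export
local_align_score <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  mat <- get_submat(params$matrix)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, scoreOnly = TRUE)
  sc <- max(0, sc)
  ka <- KA_PARAMS[[params$matrix]]
  ev <- ka["K"] * nchar(a) * nchar(b) * exp(-ka["lambda"] * sc)
  c(score = unname(sc), e_value = unname(ev))
}

#' Sequence entries for homology searches
#'
#' @param id Unique identifier.
#' @param sequence Amino-acid string.
#' @param species Species label.
#' @param kind `"full_protein"` or `"domain_instance"`.
#' @param source_domain Pfam name of the domain the entry was sliced from
#'   (domain databases), or `""`.
#' @return One-row data frame; rbind rows to form a database.
#' @export
seq_entry <- function(id, sequence, species = "", kind = "full_protein",
                      source_domain = "") {
  stopifnot(nzchar(sequence))
  data.frame(id = id, species = species, kind = kind, sequence = sequence,
             source_domain = source_domain, stringsAsFactors = FALSE)
}

# vectorized scorer: one query against many targets in a single
# pairwiseAlignment call; returns a 2-column matrix (score, e_value)
score_many <- function(query_seq, target_seqs, params = align_params()) {
  mat <- get_submat(params$matrix)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(target_seqs), Biostrings::AAString(query_seq),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  sc <- pmax(0, sc)
  ka <- KA_PARAMS[[params$matrix]]
  ev <- unname(ka["K"]) * nchar(query_seq) * nchar(target_seqs) *
    exp(-unname(ka["lambda"]) * sc)
  cbind(score = sc, e_value = ev)
}

# order: ascending e-value, ties by descending score, ties by target id
order_hits <- function(df) df[order(df$e_value, -df$score, df$target_id), ,
                              drop = FALSE]

#' Rank database hits for one query
#'
#' Scores the query against every database entry with
#' [local_align_score()] and sorts hits by ascending e-value, ties broken
#' by descending score, then lexicographic target id. A database entry
#' whose id equals the query id (an exact self-hit) is excluded.
#'
#' @param query One-row data frame ([seq_entry()]).
#' @param db Data frame of entries (non-empty after self-exclusion).
#' @param params [align_params()].
#' @param k Reciprocity depth carried on the ranking (default 3).
#' @param score_fun Optional replacement scorer
#'   `function(query_row, target_row) -> c(score, e_value)`; this is the
#'   adapter point for externally computed (e.g. BLAST tabular) searches.
#' @param exclude_self Drop the database row whose id equals the query id
#'   (default `TRUE`; cross-set reciprocal searches disable this so that a
#'   sequence present in both sets can hit itself).
#' @return Object of class `hit_ranking`: list with `query_id`, `hits`
#'   (data frame `target_id`, `score`, `e_value`), `k`.
#' @export
rank_hits <- function(query, db, params = align_params(), k = 3L,
                      score_fun = NULL, exclude_self = TRUE) {
  if (exclude_self) db <- db[db$id != query$id[1L], , drop = FALSE]
  if (nrow(db) == 0L) stopf("rank_hits: empty database")
  if (k < 1L) stopf("k must be >= 1")
  sc <- if (is.null(score_fun)) {
    score_many(query$sequence[1L], db$sequence, params)
  } else {
    t(vapply(seq_len(nrow(db)), function(i)
      score_fun(query[1L, , drop = FALSE], db[i, , drop = FALSE]),
      c(score = 0, e_value = 0)))
  }
  hits <- order_hits(data.frame(target_id = db$id, score = sc[, 1L],
                                e_value = sc[, 2L],
                                stringsAsFactors = FALSE))
  rownames(hits) <- NULL
  structure(list(query_id = query$id[1L], hits = hits, k = as.integer(k)),
            class = "hit_ranking")
}

#' @export
print.hit_ranking <- function(x, ...) {
  cat(sprintf("<hit_ranking> query %s, %d hits (k = %d)\n",
              x$query_id, nrow(x$hits), x$k))
  print(utils::head(x$hits, 5L))
  invisible(x)
}

# rank of `id` in an ordered hits data frame; tie_inclusive counts an entry
# tied (same e-value and score) with the hit at position `rank` as that rank
rank_of <- function(hits, id, tie_inclusive = TRUE) {
  pos <- match(id, hits$target_id)
  if (is.na(pos)) return(NA_integer_)
  if (!tie_inclusive) return(pos)
  tied <- hits$e_value == hits$e_value[pos] & hits$score == hits$score[pos]
  which(tied)[1L]
}

#' Relaxed reciprocal top-k good hits
#'
#' Implements the relaxed reciprocity rule used for tracing domain origins:
#' each query in `setA` is searched against `setB`; its best forward hit(s)
#' are searched back against `setA`, and a (query, target) pair is reported
#' as a *good hit* when the query appears within the first `k` hits of the
#' reverse search (sorted by e-value). `k = 3` reproduces the "within the
#' first three hits" rule; `k = 1` is classic reciprocal-best-hit. Reverse
#' hits tied with the hit at rank `k` count as within `k`.
#'
#' @param setA,setB Data frames of [seq_entry()] rows (both non-empty).
#' @param k Reverse-rank depth (default 3).
#' @param forward_depth How many forward hits of each query to test
#'   (default 1: only the best forward hit, as in a single BLAST search
#'   whose top hit is checked reciprocally).
#' @param params [align_params()].
#' @param score_fun Optional scorer override, see [rank_hits()].
#' @param tie_inclusive Count reverse ties straddling rank `k` as within
#'   `k` (default `TRUE`).
#' @return Data frame with columns `query_id`, `target_id`,
#'   `forward_rank`, `reverse_rank`.
#' @export
reciprocal_good_hits <- function(setA, setB, k = 3L, forward_depth = 1L,
                                 params = align_params(), score_fun = NULL,
                                 tie_inclusive = TRUE) {
  if (nrow(setA) == 0L || nrow(setB) == 0L)
    stopf("both sequence sets must be non-empty")
  if (k < 1L) stopf("k must be >= 1")
  rev_flip <- if (is.null(score_fun)) NULL else
    function(q, t) score_fun(t, q)
  rev_rankings <- list()
  out <- list()
  for (qi in seq_len(nrow(setA))) {
    q <- setA[qi, , drop = FALSE]
    fwd <- rank_hits(q, setB, params, k, score_fun, exclude_self = FALSE)
    depth <- min(forward_depth, nrow(fwd$hits))
    for (r in seq_len(depth)) {
      tid <- fwd$hits$target_id[r]
      if (is.null(rev_rankings[[tid]])) {
        t_row <- setB[setB$id == tid, , drop = FALSE]
        rev_rankings[[tid]] <- rank_hits(t_row, setA, params, k, rev_flip,
                                         exclude_self = FALSE)
      }
      rr <- rank_of(rev_rankings[[tid]]$hits, q$id[1L], tie_inclusive)
      if (!is.na(rr) && rr <= k)
        out[[length(out) + 1L]] <- data.frame(
          query_id = q$id[1L], target_id = tid, forward_rank = r,
          reverse_rank = rr, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(query_id = character(), target_id = character(),
               forward_rank = integer(), reverse_rank = integer(),
               stringsAsFactors = FALSE)
}

#' Reciprocal-best-hit ortholog pairs between two proteomes
#'
#' Classic strict RBH: a pair is reported when each protein is the other's
#' single top-ranked hit (positional rank 1 after deterministic
#' tie-breaking), so every protein occurs in at most one pair and the
#' result is symmetric in its arguments.
#'
#' @param proteomeA,proteomeB Data frames of [seq_entry()] rows.
#' @param params [align_params()].
#' @param score_fun Optional scorer override.
#' @return Data frame as in [reciprocal_good_hits()], restricted to
#'   mutually rank-1 pairs.
#' @export
rbh_orthologs <- function(proteomeA, proteomeB, params = align_params(),
                          score_fun = NULL) {
  gh <- reciprocal_good_hits(proteomeA, proteomeB, k = 1L,
                             forward_depth = 1L, params = params,
                             score_fun = score_fun, tie_inclusive = FALSE)
  gh[gh$forward_rank == 1L & gh$reverse_rank == 1L, , drop = FALSE]
}

#' Read / write tabular hit files (BLAST outfmt-6-like subset)
#'
#' Four tab-separated columns: query, target, score, e-value.
#' @param path File path.
#' @return Data frame with columns `query_id`, `target_id`, `score`,
#'   `e_value`.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("query_id", "target_id", "score",
                                        "e_value"),
                          stringsAsFactors = FALSE)
  df
}

#' @rdname read_hit_table
#' @param hits Data frame with the four columns above.
#' @export
write_hit_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", hits$query_id, hits$target_id,
                   format(hits$score, trim = TRUE),
                   format(hits$e_value, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Slice domain instances out of proteins to build a domain database
#'
#' Builds the per-domain sequence databases used for domain-origin
#' searches: every hit of the named domain is excised from its protein
#' sequence as one `domain_instance` entry.
#'
#' @param proteins Data frame from [read_proteome()] / [clean_isoforms()].
#' @param hits PfamScan hits for those proteins.
#' @param domain Pfam domain name to slice.
#' @return Data frame of [seq_entry()] rows (`kind = "domain_instance"`).
#' @export
domain_database <- function(proteins, hits, domain) {
  h <- hits[hits$domain_name == domain, , drop = FALSE]
  h <- h[h$protein_id %in% proteins$protein_id, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(id = character(), species = character(),
                      kind = character(), sequence = character(),
                      source_domain = character(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(h)), function(i) {
    p <- proteins[proteins$protein_id == h$protein_id[i], , drop = FALSE]
    seq_entry(sprintf("%s/%d-%d", h$protein_id[i], h$ali_start[i],
                      h$ali_end[i]),
              substr(p$sequence[1L], h$ali_start[i], h$ali_end[i]),
              species = p$species[1L], kind = "domain_instance",
              source_domain = domain)
  })
  do.call(rbind, rows)
}
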