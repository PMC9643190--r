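#' Domain arrangements
#'
#' A domain arrangement is the N- to C-terminal ordered list of Pfam domain
#' names on a protein — the unit of comparison throughout the package.
#' Domain symbols are Pfam names verbatim; `EGF` and `EGF_CA` are distinct
#' symbols and clans are never collapsed unless requested.
#'
#' @param domains Character vector of domain names, N- to C-terminal.
#' @param spans Optional two-column matrix of 1-based inclusive residue
#'   coordinates, one row per domain; must be strictly increasing and
#'   non-overlapping.
#' @param protein_id,species Identification carried along in reports.
#' @return An object of class `domain_arrangement`.
#' @export
domain_arrangement <- function(domains, spans = NULL, protein_id = "",
                               species = "") {
  domains <- as.character(domains)
  if (is.null(spans)) {
    spans <- cbind(start = integer(length(domains)),
                   end = integer(length(domains)))
  } else {
    spans <- matrix(as.integer(spans), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
  }
  if (nrow(spans) != length(domains))
    stopf("spans must have one row per domain")
  if (length(domains) > 1L && any(spans[, 1] > 0L)) {
    if (any(diff(spans[, 1]) <= 0) || any(spans[-nrow(spans), 2] >=
                                          spans[-1L, 1]))
      stopf("spans must be strictly increasing and non-overlapping")
  }
  structure(list(protein_id = protein_id, species = species,
                 domains = domains, spans = spans),
            class = "domain_arrangement")
}

#' @export
print.domain_arrangement <- function(x, ...) {
  cat(sprintf("<domain_arrangement> %s%s: %s\n", x$protein_id,
              if (nzchar(x$species)) paste0(" (", x$species, ")") else "",
              if (length(x$domains)) paste(x$domains, collapse = " – ")
              else "<empty>"))
  invisible(x)
}

#' @export
format.domain_arrangement <- function(x, ...)
  paste(x$domains, collapse = "–")

arr_symbols <- function(a) {
  if (inherits(a, "domain_arrangement")) a$domains else as.character(a)
}

#' Assemble a domain arrangement from PfamScan hits
#'
#' Filters hits by E-value (and optionally significance), sorts by alignment
#' start, and resolves overlapping hits: the hit with the lower E-value
#' wins; ties go to the higher bit score, then to the earlier start.
#'
#' @param hits Data frame of domain hits for a single protein
#'   (see [read_pfamscan()]).
#' @param evalue_max Maximum E-value retained (default 1.0; PfamScan's own
#'   gathering thresholds are assumed applied upstream).
#' @param include_insignificant Keep rows flagged significance 0
#'   (default `TRUE`).
#' @param species Species label for the arrangement.
#' @return A [domain_arrangement()] (possibly empty).
#' @export
build_arrangement <- function(hits, evalue_max = 1.0,
                              include_insignificant = TRUE, species = "") {
  if (nrow(hits) == 0L)
    return(domain_arrangement(character(), protein_id = "", species = species))
  if (length(unique(hits$protein_id)) > 1L)
    stopf("build_arrangement: hits from multiple proteins (%s)",
          paste(unique(hits$protein_id), collapse = ", "))
  keep <- hits$e_value <= evalue_max
  if (!include_insignificant && "significant" %in% names(hits))
    keep <- keep & hits$significant
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L)
    return(domain_arrangement(character(), protein_id = hits$protein_id[1L],
                              species = species))
  # overlap resolution: accept in priority order, drop hits overlapping an
  # already accepted one
  pri <- order(h$e_value, -h$bit_score, h$ali_start, h$domain_name)
  acc <- logical(nrow(h))
  for (i in pri) {
    ov <- acc & (h$ali_start <= h$ali_end[i]) & (h$ali_end >= h$ali_start[i])
    if (!any(ov)) acc[i] <- TRUE
  }
  h <- h[acc, , drop = FALSE]
  h <- h[order(h$ali_start), , drop = FALSE]
  domain_arrangement(h$domain_name, cbind(h$ali_start, h$ali_end),
                     protein_id = h$protein_id[1L], species = species)
}

# Levenshtein DP over symbol vectors, returning distance and an edit script.
# ops: "match", "sub", "ins" (symbol present in b only), "del" (in a only).
lev_align <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  if (n && m) {
    for (i in 1:n) for (j in 1:m) {
      d[i + 1L, j + 1L] <- min(d[i, j] + (a[i] != b[j]),
                               d[i, j + 1L] + 1L, d[i + 1L, j] + 1L)
    }
  }
  # traceback (prefer diagonal, then deletion, then insertion)
  i <- n; j <- m
  ops <- character(0); pos <- integer(0); sym <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && d[i + 1L, j + 1L] == d[i, j] + (a[i] != b[j])) {
      ops <- c(if (a[i] != b[j]) "sub" else "match", ops)
      pos <- c(i, pos); sym <- c(b[j], sym)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && d[i + 1L, j + 1L] == d[i, j + 1L] + 1L) {
      ops <- c("del", ops); pos <- c(i, pos); sym <- c(a[i], sym)
      i <- i - 1L
    } else {
      ops <- c("ins", ops); pos <- c(i + 1L, pos); sym <- c(b[j], sym)
      j <- j - 1L
    }
  }
  list(distance = d[n + 1L, m + 1L],
       script = data.frame(position = pos, domain_name = sym, op = ops,
                           stringsAsFactors = FALSE))
}

#' Edit distance between two domain arrangements
#'
#' Levenshtein distance over the domain-symbol strings with unit costs for
#' substitution, insertion and deletion. It is a metric on symbol strings.
#'
#' @param a,b [domain_arrangement()]s or plain character vectors of symbols.
#' @return Non-negative integer distance.
#' @export
arrangement_distance <- function(a, b) {
  lev_align(arr_symbols(a), arr_symbols(b))$distance
}

DIFF_KINDS <- c("identical", "repeat_count_change", "terminal_gain_N",
                "terminal_gain_C", "terminal_loss_N", "terminal_loss_C",
                "internal_insertion", "internal_deletion", "complex",
                "unrelated")

#' Classify the difference between two domain arrangements
#'
#' Computes a minimal symbol-level edit alignment of `a` onto `b` and maps
#' it to the event vocabulary of modular protein evolution. The rubric, in
#' order of precedence:
#'
#' 1. equal symbol strings → `identical`;
#' 2. no shared symbol → `unrelated`;
#' 3. identical run symbols in the repeat profiles, only counts differ →
#'    `repeat_count_change`;
#' 4. edits confined to one terminus, all insertions → `terminal_gain_N/C`;
#'    all deletions → `terminal_loss_N/C`;
#' 5. a single contiguous internal run of insertions (resp. deletions) →
#'    `internal_insertion` / `internal_deletion`;
#' 6. anything else → `complex`.
#'
#' Direction is a → b (an "insertion" is a domain present only in `b`).
#'
#' @param a,b [domain_arrangement()]s or character vectors.
#' @return An object of class `arrangement_diff` with fields `kind`,
#'   `edit_distance` and `details` (the edit script).
#' @export
classify_difference <- function(a, b) {
  sa <- arr_symbols(a); sb <- arr_symbols(b)
  al <- lev_align(sa, sb)
  edits <- al$script[al$script$op != "match", , drop = FALSE]
  kind <- if (al$distance == 0L) "identical"
    else if (length(intersect(sa, sb)) == 0L) "unrelated"
    else classify_edits(sa, sb, al$script)
  structure(list(kind = kind, edit_distance = al$distance, details = edits),
            class = "arrangement_diff")
}

classify_edits <- function(sa, sb, script) {
  ra <- rle(sa); rb <- rle(sb)
  if (identical(ra$values, rb$values)) return("repeat_count_change")
  is_edit <- script$op != "match"
  idx <- which(is_edit)
  ops <- unique(script$op[idx])
  contiguous <- all(diff(idx) == 1L)
  if (contiguous && length(ops) == 1L && ops %in% c("ins", "del")) {
    at_n <- idx[1L] == 1L
    at_c <- idx[length(idx)] == nrow(script)
    if (ops == "ins") {
      if (at_n) return("terminal_gain_N")
      if (at_c) return("terminal_gain_C")
      return("internal_insertion")
    } else {
      if (at_n) return("terminal_loss_N")
      if (at_c) return("terminal_loss_C")
      return("internal_deletion")
    }
  }
  "complex"
}

#' @export
print.arrangement_diff <- function(x, ...) {
  cat(sprintf("<arrangement_diff> %s (edit distance %d)\n",
              x$kind, x$edit_distance))
  if (nrow(x$details)) print(x$details)
  invisible(x)
}

#' Run-length repeat profile of an arrangement
#'
#' Collapses tandem repeats of the same domain into (name, count) runs,
#' e.g. the plasma kallikrein / factor XI arrangement
#' `PAN_1, PAN_1, PAN_1, PAN_1, Trypsin` profiles as `PAN_1 x4; Trypsin x1`.
#'
#' @param a A [domain_arrangement()] or character vector.
#' @return Object of class `repeat_profile`: data frame with columns
#'   `domain_name`, `count`.
#' @export
repeat_profile <- function(a) {
  s <- arr_symbols(a)
  r <- rle(s)
  structure(data.frame(domain_name = as.character(r$values),
                       count = as.integer(r$lengths),
                       stringsAsFactors = FALSE),
            class = c("repeat_profile", "data.frame"))
}

#' Expand a repeat profile back into the full symbol vector
#' @param profile A `repeat_profile`.
#' @return Character vector of domain symbols.
#' @export
expand_repeat_profile <- function(profile) {
  rep(profile$domain_name, profile$count)
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("<repeat_profile>",
      paste(sprintf("%s ×%d", x$domain_name, x$count), collapse = "; "),
      "\n")
  invisible(x)
}

#' Domain symbols shared by two arrangements
#'
#' @param a,b [domain_arrangement()]s or character vectors.
#' @return Character vector (set) of shared domain names, sorted.
#' @export
shared_domains <- function(a, b) {
  sort(intersect(arr_symbols(a), arr_symbols(b)))
}

#' Write an arrangement report table
#'
#' One row per protein: species, protein id, arrangement (symbols joined by
#' an en dash) and the repeat profile (`name`×`count`, semicolon-joined).
#'
#' @param arrangements List of [domain_arrangement()]s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_arrangement_report <- function(arrangements, path) {
  rows <- vapply(arrangements, function(a) {
    pr <- repeat_profile(a)
    paste(a$species, a$protein_id,
          paste(a$domains, collapse = "–"),
          paste(sprintf("%s×%d", pr$domain_name, pr$count),
                collapse = ";"),
          sep = "\t")
  }, "")
  writeLines(c("species\tprotein_id\tarrangement\trepeat_profile", rows),
             path)
  invisible(path)
}
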