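#' Header dialects for proteome FASTA files
#'
#' Proteome FASTA files from the major archives tag the parent gene of each
#' protein differently. A dialect bundles a name with a regular expression
#' whose single capture group extracts the gene identifier from a record
#' header. Built-in dialects:
#'
#' * `ensembl` — `gene[:= ]\s*(\S+)`, matching `gene:ENSG...` tags.
#' * `uniprot` — `GN[:= ]\s*(\S+)`, matching `GN=F2` tags.
#' * `ncbi`    — `\[gene=...\]` bracket tags; headers without the tag fall
#'   back to protein-id-as-gene, mirroring how RefSeq protein sets are
#'   commonly reduced.
#' * `custom`  — any user-supplied regex with exactly one capture group.
#'
#' @param name One of `"ensembl"`, `"uniprot"`, `"ncbi"`, or `"custom"`.
#' @param gene_regex For `custom`, a PCRE with exactly one capture group.
#' @return An object of class `header_dialect`.
#' @examples
#' parse_gene_id("ENSP001 pep gene:ENSG42 transcript:ENST7",
#'               header_dialect("ensembl"))
#' @export
header_dialect <- function(name = c("ensembl", "uniprot", "ncbi", "custom"),
                           gene_regex = NULL) {
  name <- match.arg(name)
  regex <- switch(name,
    ensembl = "gene[:= ]\\s*(\\S+)",
    uniprot = "GN[:= ]\\s*(\\S+)",
    ncbi    = "\\[gene=([^]\\s]+)\\]",
    custom  = gene_regex
  )
  if (is.null(regex))
    stopf("custom dialect requires a gene_regex")
  ok <- tryCatch({ regexpr(regex, "probe", perl = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("invalid regex in dialect: %s", regex)
  # exactly one capture group (count unescaped '(' not starting '(?')
  stripped <- gsub("\\\\.", "", regex)
  ngroups <- lengths(regmatches(stripped, gregexpr("\\((?!\\?)", stripped,
                                                   perl = TRUE)))
  if (ngroups != 1L)
    stopf("dialect regex must have exactly one capture group, found %d", ngroups)
  structure(list(name = name, gene_regex = regex), class = "header_dialect")
}

#' @export
print.header_dialect <- function(x, ...) {
  cat(sprintf("<header_dialect> %s: %s\n", x$name, x$gene_regex))
  invisible(x)
}

#' Extract a gene id from a FASTA header
#'
#' Applies the dialect's regex and returns the first capture group. Headers
#' without a match fall back to the first whitespace-delimited token, i.e.
#' the protein is treated as its own gene.
#'
#' @param header A FASTA header line (with or without the leading `>`).
#' @param dialect A [header_dialect()].
#' @return The gene id as a character scalar.
#' @export
parse_gene_id <- function(header, dialect) {
  if (!inherits(dialect, "header_dialect"))
    stopf("dialect must be a header_dialect")
  if (!is.character(header) || length(header) != 1L || !nzchar(header))
    stopf("header must be a non-empty string")
  header <- sub("^>", "", header)
  m <- regexpr(dialect$gene_regex, header, perl = TRUE)
  if (m[1L] != -1L) {
    st <- attr(m, "capture.start")[1L]
    len <- attr(m, "capture.length")[1L]
    if (!is.na(st) && st > 0L) return(substr(header, st, st + len - 1L))
  }
  strsplit(header, "\\s+")[[1L]][1L]
}

#' Read a proteome FASTA file
#'
#' Loads every record, derives the gene id of each protein from its header
#' using the given dialect, and sanitizes sequences (any `*` is stripped
#' with a warning; letters outside the 20 standard residues are mapped to
#' `X`).
#'
#' @param path FASTA file (plain or gzipped).
#' @param dialect A [header_dialect()] or a dialect name.
#' @param species Species label attached to every record.
#' @return A data frame with columns `protein_id`, `gene_id`, `species`,
#'   `sequence` — one row per FASTA record.
#' @export
read_proteome <- function(path, dialect = header_dialect("ensembl"),
                          species = "unknown") {
  if (is.character(dialect)) dialect <- header_dialect(dialect)
  if (!file.exists(path)) stopf("proteome file not found: %s", path)
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  pid <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  gid <- vapply(headers, parse_gene_id, "", dialect = dialect,
                USE.NAMES = FALSE)
  seqs <- as.character(ss)
  seqs <- vapply(seq_along(seqs), function(i) sanitize_aa(seqs[i], pid[i]), "")
  if (anyDuplicated(pid))
    stopf("duplicate protein ids in %s", path)
  data.frame(protein_id = pid, gene_id = gid, species = species,
             sequence = seqs, stringsAsFactors = FALSE, row.names = NULL)
}

#' Reduce a proteome to one (longest) isoform per gene
#'
#' For each `gene_id` the longest sequence is retained; equal-length ties
#' are broken by the lexicographically smallest `protein_id`, so the result
#' is deterministic. The operation is idempotent.
#'
#' @param proteins Data frame as returned by [read_proteome()].
#' @return Data frame with exactly one row per gene, ordered by `gene_id`.
#' @export
clean_isoforms <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  if (length(unique(proteins$species)) > 1L)
    stopf("clean_isoforms expects records from a single species")
  len <- nchar(proteins$sequence)
  ord <- order(proteins$gene_id, -len, proteins$protein_id)
  p <- proteins[ord, , drop = FALSE]
  p <- p[!duplicated(p$gene_id), , drop = FALSE]
  rownames(p) <- NULL
  p
}

# PfamScan tabular layout: 15 whitespace-separated columns, '#' comments.
PFAMSCAN_COLS <- c("protein_id", "ali_start", "ali_end", "env_start",
                   "env_end", "hmm_acc", "domain_name", "type", "hmm_start",
                   "hmm_end", "hmm_length", "bit_score", "e_value",
                   "significance", "clan")

#' Read a PfamScan-style domain hit table
#'
#' Parses the standard `pfam_scan.pl` tabular output: comment lines starting
#' with `#`, then whitespace-separated columns (sequence id, alignment
#' start/end, envelope start/end, HMM accession, HMM name, type, HMM
#' start/end/length, bit score, E-value, significance, clan). Coordinates
#' are kept 1-based inclusive. Rows with significance 0 are retained and
#' flagged via the logical `significant` column.
#'
#' @param path Path to the table.
#' @return A data frame of domain hits with typed columns plus
#'   `significant`.
#' @export
read_pfamscan <- function(path) {
  if (!file.exists(path)) stopf("PfamScan file not found: %s", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  hits <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 14L)
      stopf("malformed PfamScan row at line %d of %s (%d fields)",
            i, path, length(f))
    if (length(f) == 14L) f <- c(f, "")   # clan column may be empty
    num <- suppressWarnings(as.numeric(f[c(2:5, 9:14)]))
    if (anyNA(num))
      stopf("malformed PfamScan row at line %d of %s (non-numeric field)",
            i, path)
    hits[[j]] <- data.frame(
      protein_id = f[1L], ali_start = as.integer(f[2L]),
      ali_end = as.integer(f[3L]), env_start = as.integer(f[4L]),
      env_end = as.integer(f[5L]), hmm_acc = f[6L], domain_name = f[7L],
      type = f[8L], hmm_start = as.integer(f[9L]),
      hmm_end = as.integer(f[10L]), hmm_length = as.integer(f[11L]),
      bit_score = as.numeric(f[12L]), e_value = as.numeric(f[13L]),
      significance = as.integer(f[14L]),
      clan = if (f[15L] %in% c("-", "")) "" else f[15L],
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 15)), PFAMSCAN_COLS)
  bad <- with(out, ali_start > ali_end | env_start > ali_start |
                   ali_end > env_end | e_value < 0)
  if (any(bad))
    stopf("inconsistent coordinates/e-value in %s (first bad data row %d)",
          path, which(bad)[1L])
  out$significant <- out$significance != 0L
  out
}

#' Write domain hits in PfamScan tabular layout
#'
#' Inverse of [read_pfamscan()]: the reader applied to the written file
#' reproduces all fields exactly.
#'
#' @param hits Data frame of domain hits (see [read_pfamscan()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfamscan <- function(hits, path) {
  hdr <- "# <seq id> <alignment start> <alignment end> <envelope start> <envelope end> <hmm acc> <hmm name> <type> <hmm start> <hmm end> <hmm length> <bit score> <E-value> <significance> <clan>"
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(h$protein_id, h$ali_start, h$ali_end, h$env_start, h$env_end,
          h$hmm_acc, h$domain_name, h$type, h$hmm_start, h$hmm_end,
          h$hmm_length, format(h$bit_score, trim = TRUE),
          format(h$e_value, trim = TRUE, scientific = NA), h$significance,
          if (nzchar(h$clan)) h$clan else "-", sep = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
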