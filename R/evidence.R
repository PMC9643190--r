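#' Read a gene-order table
#'
#' Tab-separated with header: `species`, `scaffold`, `gene_id`, `start`,
#' `end`, `strand`. Coordinates are 1-based inclusive base pairs.
#'
#' @param path TSV path.
#' @return Data frame of gene loci.
#' @export
read_gene_order <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "integer", "integer",
                                         "character"))
  need <- c("species", "scaffold", "gene_id", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stopf("gene-order table must have columns: %s", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stopf("gene locus with start > end in %s", path)
  df
}

#' @rdname read_gene_order
#' @param order Data frame of gene loci.
#' @export
write_gene_order <- function(order, path) {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s", order$species, order$scaffold,
                   order$gene_id, order$start, order$end, order$strand)
  writeLines(c("species\tscaffold\tgene_id\tstart\tend\tstrand", lines), path)
  invisible(path)
}

SYNTENY_STATES <- c("conserved_with_candidate", "locus_present_gene_missing",
                    "flanks_split", "flanks_missing")

synteny_result <- function(state, left_flank = NA_character_,
                           right_flank = NA_character_, details = "") {
  stopifnot(state %in% SYNTENY_STATES)
  structure(list(state = state, left_flank = left_flank,
                 right_flank = right_flank, details = details),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("<synteny_result> %s [flanks %s | %s] %s\n", x$state,
              x$left_flank, x$right_flank, x$details))
  invisible(x)
}

#' Flanking-gene synteny check for a missing gene
#'
#' Identifies the nearest neighbours of `gene` on its reference scaffold,
#' maps them into the target species via `ortholog_map`, and classifies the
#' neighbourhood:
#'
#' * both flank orthologs on one target scaffold with 1..`gap_genes` genes
#'   between them → `conserved_with_candidate` (a candidate gene sits where
#'   the missing gene should be);
#' * flank orthologs directly adjacent (nothing between) →
#'   `locus_present_gene_missing`;
#' * flank orthologs on different scaffolds (or further apart than
#'   `gap_genes`) → `flanks_split`;
#' * one or both flanks unmapped or absent → `flanks_missing`.
#'
#' The classification only uses gene order, so it is invariant to reversing
#' a scaffold together with its strand annotations.
#'
#' @param reference_order Gene loci of the reference species
#'   (see [read_gene_order()]).
#' @param target_order Gene loci of the target species.
#' @param gene Reference gene id whose neighbourhood is tested.
#' @param ortholog_map Named character vector, reference gene id →
#'   target gene id (possibly partial).
#' @param gap_genes Maximum intervening genes for flanks to count as
#'   adjacent (default 3).
#' @return A `synteny_result`.
#' @export
synteny_check <- function(reference_order, target_order, gene, ortholog_map,
                          gap_genes = 3L) {
  ri <- which(reference_order$gene_id == gene)
  if (length(ri) == 0L)
    stopf("gene %s not present in the reference gene order", gene)
  ri <- ri[1L]
  scaf <- reference_order$scaffold[ri]
  neigh <- reference_order[reference_order$scaffold == scaf, , drop = FALSE]
  neigh <- neigh[order(neigh$start), , drop = FALSE]
  pos <- which(neigh$gene_id == gene)
  left <- if (pos > 1L) neigh$gene_id[pos - 1L] else NA_character_
  right <- if (pos < nrow(neigh)) neigh$gene_id[pos + 1L] else NA_character_
  lt <- if (!is.na(left)) unname(ortholog_map[left]) else NA_character_
  rt <- if (!is.na(right)) unname(ortholog_map[right]) else NA_character_
  if (is.na(lt) || is.na(rt) ||
      !(lt %in% target_order$gene_id) || !(rt %in% target_order$gene_id))
    return(synteny_result("flanks_missing", left, right,
                          "flank ortholog unmapped or absent from target"))
  tl <- target_order[target_order$gene_id == lt, , drop = FALSE][1L, ]
  tr <- target_order[target_order$gene_id == rt, , drop = FALSE][1L, ]
  if (tl$scaffold != tr$scaffold)
    return(synteny_result("flanks_split", left, right,
                          sprintf("flank orthologs on scaffolds %s and %s",
                                  tl$scaffold, tr$scaffold)))
  tsc <- target_order[target_order$scaffold == tl$scaffold, , drop = FALSE]
  tsc <- tsc[order(tsc$start), , drop = FALSE]
  p1 <- which(tsc$gene_id == lt); p2 <- which(tsc$gene_id == rt)
  between <- tsc$gene_id[seq(min(p1, p2) + 1L, length.out =
                             max(abs(p2 - p1) - 1L, 0L))]
  n_between <- length(between)
  if (n_between == 0L)
    return(synteny_result("locus_present_gene_missing", left, right,
                          "flank orthologs directly adjacent"))
  if (n_between <= gap_genes)
    return(synteny_result("conserved_with_candidate", left, right,
                          sprintf("candidate gene(s) between flanks: %s",
                                  paste(between, collapse = ","))))
  synteny_result("flanks_split", left, right,
                 sprintf("flanks on one scaffold but %d genes apart",
                         n_between))
}

#' Scan a genomic region for a degraded (pseudogenized) protein copy
#'
#' Translates the genomic sequence in the three forward frames, locally
#' aligns each translation against the protein (stop codons score as strong
#' mismatches and are aligned through rather than breaking the alignment),
#' picks the best-scoring frame, and reports the aligned fraction of the
#' protein and the number of stop codons inside the aligned span. The model
#' is single-frame and intron-free (see the package vignette); frameshifts
#' are not modelled, so `frameshift_breaks` is always 0.
#'
#' @param protein Amino-acid string.
#' @param genomic DNA string (A/C/G/T/N), length >= 3. Reverse-strand genes
#'   should be reverse-complemented before calling.
#' @param params [align_params()] used for the protein-translation
#'   alignment.
#' @return Object of class `pseudogene_scan`: list with `aligned_fraction`
#'   (protein residues covered / protein length), `premature_stops`,
#'   `frameshift_breaks`, `frame` and `score`.
#' @export
pseudogene_scan <- function(protein, genomic, params = align_params()) {
  genomic <- toupper(genomic)
  if (grepl("[^ACGTN]", genomic))
    stopf("genomic sequence contains characters outside ACGTN")
  if (nchar(genomic) < 3L) stopf("genomic sequence shorter than one codon")
  protein <- toupper(protein)
  mat <- get_submat(params$matrix)
  best <- NULL
  for (frame in 1:3) {
    n <- nchar(genomic) - frame + 1L
    if (n < 3L) next
    sub <- substr(genomic, frame, frame + (n %/% 3L) * 3L - 1L)
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
    if (!nzchar(aa)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(protein), Biostrings::AAString(aa),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    if (is.null(best) || Biostrings::score(pa) > best$score)
      best <- list(score = Biostrings::score(pa), frame = frame, pa = pa)
  }
  if (is.null(best) || best$score <= 0)
    return(structure(list(aligned_fraction = 0, premature_stops = 0L,
                          frameshift_breaks = 0L, frame = NA_integer_,
                          score = 0),
                     class = "pseudogene_scan"))
  pa <- best$pa
  pat_rng <- c(Biostrings::start(Biostrings::pattern(pa)),
               Biostrings::end(Biostrings::pattern(pa)))
  aligned_fraction <- (pat_rng[2L] - pat_rng[1L] + 1L) / nchar(protein)
  subj_aln <- as.character(Biostrings::alignedSubject(pa))
  stops <- lengths(regmatches(subj_aln, gregexpr("\\*", subj_aln)))
  structure(list(aligned_fraction = aligned_fraction,
                 premature_stops = as.integer(stops),
                 frameshift_breaks = 0L, frame = best$frame,
                 score = best$score),
            class = "pseudogene_scan")
}

#' @export
print.pseudogene_scan <- function(x, ...) {
  cat(sprintf(paste0("<pseudogene_scan> frame %s, aligned fraction %.2f, ",
                     "%d premature stop(s)\n"),
              x$frame, x$aligned_fraction, x$premature_stops))
  invisible(x)
}

GENE_STATUS <- c("present", "lost", "ambiguous", "pseudogene")

#' Resolve gene status from ortholog, synteny and pseudogene evidence
#'
#' Total decision table combining the three evidence lines for one
#' (gene, species) pair:
#'
#' * ortholog found and no scan (or a clean scan, 0 premature stops) →
#'   `present`;
#' * ortholog found, scan with >= `stops_min` premature stops over >=
#'   `cov_min` of the protein → `pseudogene`;
#' * no ortholog, flanking-gene synteny showing the locus without the gene
#'   (`locus_present_gene_missing` or `flanks_split`), and no scan or scan
#'   coverage below `cov_min` → `lost` (forced to `ambiguous` when
#'   `clade_hit` reports a match elsewhere in the surrounding clade);
#' * any other combination → `ambiguous`.
#'
#' @param ortholog_found Logical: did the homology search find a reciprocal
#'   ortholog?
#' @param synteny A `synteny_result`, or `NULL` if not assessed.
#' @param scan A `pseudogene_scan`, or `NULL` if not performed.
#' @param thresholds List with `cov_min` (default 0.5) and `stops_min`
#'   (default 1).
#' @param clade_hit Optional logical: a search of the wider clade found the
#'   gene, so absence in this assembly is not decisive.
#' @return One of `"present"`, `"lost"`, `"ambiguous"`, `"pseudogene"`.
#' @export
call_gene_status <- function(ortholog_found, synteny = NULL, scan = NULL,
                             thresholds = list(cov_min = 0.5, stops_min = 1L),
                             clade_hit = FALSE) {
  cov_min <- thresholds$cov_min %||% 0.5
  stops_min <- thresholds$stops_min %||% 1L
  if (isTRUE(ortholog_found)) {
    if (is.null(scan) || scan$premature_stops == 0L) return("present")
    if (scan$premature_stops >= stops_min &&
        scan$aligned_fraction >= cov_min) return("pseudogene")
    return("ambiguous")
  }
  synteny_absent <- !is.null(synteny) &&
    synteny$state %in% c("locus_present_gene_missing", "flanks_split")
  scan_weak <- is.null(scan) || scan$aligned_fraction < cov_min
  if (synteny_absent && scan_weak) {
    if (isTRUE(clade_hit)) return("ambiguous")
    return("lost")
  }
  "ambiguous"
}

#' Bundle evidence for one (gene, species) pair
#'
#' Convenience constructor that resolves the status with
#' [call_gene_status()] and keeps the inputs for reporting.
#'
#' @inheritParams call_gene_status
#' @param gene_id,species Identification.
#' @return Object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(gene_id, species, ortholog_found, synteny = NULL,
                            scan = NULL,
                            thresholds = list(cov_min = 0.5, stops_min = 1L),
                            clade_hit = FALSE) {
  status <- call_gene_status(ortholog_found, synteny, scan, thresholds,
                             clade_hit)
  structure(list(gene_id = gene_id, species = species,
                 ortholog_found = ortholog_found, synteny = synteny,
                 scan = scan, status = status),
            class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("<evidence_bundle> %s / %s: %s (ortholog %s)\n", x$gene_id,
              x$species, x$status, if (x$ortholog_found) "yes" else "no"))
  invisible(x)
}
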