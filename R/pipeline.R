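#' Configuration for an end-to-end pipeline run
#'
#' @param dir Dataset directory as written by [simulate_dataset()] or
#'   [coagulation_fixture()]: per-species `<sp>.proteome.fa`,
#'   `<sp>.pfamscan.tsv`, `<sp>.gene_order.tsv`, optional
#'   `<sp>.genomic.fa`, plus `tree.nwk` and `dataset.json` (species list,
#'   header dialects, optional clade-hit records).
#' @param out_dir Report output directory.
#' @param reference Reference species whose gene set is traced across all
#'   others; defaults to the last species in the dataset manifest.
#' @param k Reverse-rank depth for relaxed reciprocal searches (the
#'   pipeline's ortholog calls use strict reciprocal best hits; `k` is
#'   recorded for the manifest and used by downstream good-hit reports).
#' @param align [align_params()].
#' @param thresholds Evidence thresholds: `cov_min`, `stops_min`,
#'   `gap_genes`.
#' @param evalue_max E-value cutoff for arrangement building.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, out_dir, reference = NULL, k = 3L,
                            align = align_params(),
                            thresholds = list(cov_min = 0.5,
                                              stops_min = 1L,
                                              gap_genes = 3L),
                            evalue_max = 1.0, seed = 1L) {
  if (k < 1L) stopf("k must be >= 1")
  structure(list(dir = dir, out_dir = out_dir, reference = reference,
                 k = as.integer(k), align = align, thresholds = thresholds,
                 evalue_max = evalue_max, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_dataset_manifest <- function(dir) {
  path <- file.path(dir, "dataset.json")
  if (!file.exists(path)) stopf("dataset manifest not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

read_genomic <- function(path) {
  if (!file.exists(path)) return(NULL)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss),
                  vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L))
}

#' Run the full comparative pipeline on a dataset directory
#'
#' Executes ingest → arrangements → homology → evidence → Dollo mapping:
#'
#' 1. per species, reads the proteome (in its header dialect), keeps the
#'    longest isoform per gene, parses the PfamScan table and assembles
#'    domain arrangements;
#' 2. writes an arrangement report and a domain-by-species incidence
#'    matrix;
#' 3. finds reciprocal-best-hit orthologs of every reference gene in every
#'    other species;
#' 4. for genes without an ortholog, runs the flanking-gene synteny check
#'    and, where a matching genomic region is available, the
#'    premature-stop scan, then resolves a status per (gene, species);
#' 5. converts statuses into a presence matrix (`present` → `+`,
#'    `lost`/`pseudogene` → `-`, `ambiguous` → `?`), restricted to species
#'    on the tree (outgroups are used for homology only), and maps every
#'    column under Dollo parsimony.
#'
#' The run is deterministic for fixed inputs; the only timestamp lives in
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `arrangements`, `orthologs`, `status`,
#'   `presence`, `assignments`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  ds <- read_dataset_manifest(config$dir)
  species <- unlist(ds$species)
  if (length(species) == 0L) stopf("no input proteomes")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- ape::read.tree(file.path(config$dir, "tree.nwk"))
  reference <- config$reference %||% species[length(species)]
  if (!reference %in% species)
    stopf("reference species '%s' not in dataset", reference)

  # ---- ingest + arrangements
  proteomes <- list(); hits <- list(); arrangements <- list()
  orders <- list(); genomic <- list()
  log <- list()
  for (sp in species) {
    dialect <- ds$dialects[[sp]] %||% "ensembl"
    prot <- read_proteome(file.path(config$dir, paste0(sp, ".proteome.fa")),
                          dialect, species = sp)
    n_in <- nrow(prot)
    prot <- clean_isoforms(prot)
    proteomes[[sp]] <- prot
    h <- read_pfamscan(file.path(config$dir, paste0(sp, ".pfamscan.tsv")))
    hits[[sp]] <- h
    for (pid in prot$protein_id) {
      ph <- h[h$protein_id == pid, , drop = FALSE]
      if (nrow(ph) == 0L) next
      arrangements[[paste(sp, pid)]] <-
        build_arrangement(ph, evalue_max = config$evalue_max, species = sp)
    }
    op <- file.path(config$dir, paste0(sp, ".gene_order.tsv"))
    if (file.exists(op)) orders[[sp]] <- read_gene_order(op)
    genomic[[sp]] <- read_genomic(file.path(config$dir,
                                            paste0(sp, ".genomic.fa")))
    log[[length(log) + 1L]] <- list(stage = "ingest", species = sp,
                                    records_in = n_in,
                                    genes_out = nrow(prot))
  }
  write_arrangement_report(unname(arrangements),
                           file.path(config$out_dir, "arrangements.tsv"))

  # domain-by-species incidence (Table-1 style)
  all_domains <- sort(unique(unlist(lapply(arrangements, `[[`, "domains"))))
  dm <- matrix("", length(all_domains), length(species),
               dimnames = list(all_domains, species))
  for (a in arrangements)
    dm[unique(a$domains), a$species] <- "✓"
  writeLines(c(paste(c("domain", species), collapse = "\t"),
               vapply(seq_along(all_domains), function(i)
                 paste(c(all_domains[i], dm[i, ]), collapse = "\t"), "")),
             file.path(config$out_dir, "domains_by_species.tsv"))

  # ---- homology: reference genes traced into every species
  ref <- proteomes[[reference]]
  ref_entries <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i)
    seq_entry(ref$protein_id[i], ref$sequence[i], species = reference)))
  ortho <- list()      # species -> named chr vector ref_gene -> target_gene
  for (sp in setdiff(species, reference)) {
    tgt <- proteomes[[sp]]
    tgt_entries <- do.call(rbind, lapply(seq_len(nrow(tgt)), function(i)
      seq_entry(tgt$protein_id[i], tgt$sequence[i], species = sp)))
    pairs <- rbh_orthologs(ref_entries, tgt_entries, params = config$align)
    ref_gene <- ref$gene_id[match(pairs$query_id, ref$protein_id)]
    tgt_gene <- tgt$gene_id[match(pairs$target_id, tgt$protein_id)]
    ortho[[sp]] <- stats::setNames(tgt_gene, ref_gene)
    log[[length(log) + 1L]] <- list(stage = "homology", species = sp,
                                    pairs = nrow(pairs))
  }

  # ---- evidence + presence
  clade_hits <- ds$clade_hits
  has_clade_hit <- function(sp, gene) {
    !is.null(clade_hits) && nrow(as.data.frame(clade_hits)) > 0L &&
      any(clade_hits$species == sp & clade_hits$gene == gene)
  }
  tips <- tree$tip.label
  eval_species <- intersect(species, tips)
  ref_genes <- sort(ref$gene_id)
  presence <- matrix("?", length(eval_species), length(ref_genes),
                     dimnames = list(eval_species, ref_genes))
  status_rows <- list()
  for (sp in eval_species) {
    for (g in ref_genes) {
      if (sp == reference) {
        st <- "present"; of <- TRUE; syn <- NULL; scan <- NULL
      } else {
        of <- !is.na(unname(ortho[[sp]][g]))
        scan <- NULL
        gseq <- genomic[[sp]][paste0("GENE_", g)]
        gseq <- if (length(gseq) == 1L && !is.na(gseq)) unname(gseq) else NULL
        if (!is.null(gseq)) {
          rp <- ref$sequence[ref$gene_id == g][1L]
          scan <- pseudogene_scan(rp, gseq, config$align)
        }
        syn <- NULL
        if (!of && !is.null(orders[[reference]]) && !is.null(orders[[sp]]))
          syn <- synteny_check(orders[[reference]], orders[[sp]], g,
                               ortho[[sp]],
                               config$thresholds$gap_genes %||% 3L)
        st <- call_gene_status(of, syn, scan, config$thresholds,
                               clade_hit = has_clade_hit(sp, g))
      }
      presence[sp, g] <- switch(st, present = "+", pseudogene = "-",
                                lost = "-", ambiguous = "?")
      status_rows[[length(status_rows) + 1L]] <- data.frame(
        gene = g, species = sp, status = st,
        ortholog_found = of,
        synteny = if (is.null(syn)) "" else syn$state,
        aligned_fraction = if (is.null(scan)) NA_real_ else
          round(scan$aligned_fraction, 4),
        premature_stops = if (is.null(scan)) NA_integer_ else
          scan$premature_stops,
        stringsAsFactors = FALSE)
    }
  }
  status <- do.call(rbind, status_rows)
  utils::write.table(status, file.path(config$out_dir, "status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_presence_matrix(presence, file.path(config$out_dir, "presence.tsv"))

  # ---- Dollo mapping
  assignments <- dollo_map_all(presence, tree)
  write_gainloss_report(assignments,
                        file.path(config$out_dir, "gainloss.tsv"))
  write_annotated_newick(assignments, tree,
                         file.path(config$out_dir, "annotated_tree.nwk"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("domarch")),
    timestamp = format(Sys.time(), tz = "UTC"),
    parameters = list(reference = reference, k = config$k,
                      matrix = config$align$matrix,
                      gap_open = config$align$gap_open,
                      gap_extend = config$align$gap_extend,
                      thresholds = config$thresholds,
                      evalue_max = config$evalue_max,
                      seed = config$seed),
    stages = log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(arrangements = arrangements,
                 orthologs = ortho, status = status, presence = presence,
                 assignments = assignments, out_dir = config$out_dir))
}
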