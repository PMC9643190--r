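# ---- deterministic sequence material ---------------------------------------

# Typical lengths for recurring coagulation-cascade Pfam families; anything
# else defaults to 60 residues.
DOMAIN_LENGTHS <- c(Gla = 40, EGF = 38, EGF_CA = 40, Kringle = 80,
                    PAN_1 = 85, Trypsin = 220, FXa_inhibition = 45,
                    Thrombin_light = 36, fn1 = 45, fn2 = 50,
                    Transglut_N = 120, Transglut_core = 150,
                    Transglut_C = 90, VWD = 160, TIL = 50, C8 = 70,
                    VWA = 170, VWC = 60, Sushi = 56, `Cu-oxidase` = 140,
                    F5_F8_type_C = 150, Laminin_G_1 = 160, Laminin_G_2 = 150,
                    Ldl_recept_b = 42)

LINKER <- "GS"

#' Deterministic base sequence for a domain family
#'
#' Every domain family has a fixed pseudo-random amino-acid sequence derived
#' from its name, so two instances of the same family are identical at the
#' root of a simulation (and diverge only through simulated substitutions),
#' while different families are unrelated random sequences.
#'
#' @param name Domain (Pfam family) name.
#' @return Amino-acid string.
#' @export
domain_base_seq <- function(name) {
  len <- DOMAIN_LENGTHS[name]
  if (is.na(len)) len <- 60L
  seed <- derive_seed(sum(utf8ToInt(name) * seq_along(utf8ToInt(name))), 991L)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  withr_seed(function() paste(sample(AA20, len, replace = TRUE),
                              collapse = ""))
}

# Fixed codon per amino acid (most frequent human codon); X -> NNN.
CODON_TABLE <- c(A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC",
                 Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
                 L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
                 S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG",
                 X = "NNN", `*` = "TAA")

#' Back-translate a protein with a fixed codon table
#'
#' Uses one codon per amino acid (the most frequent human codon), so the
#' result is deterministic and translates back to the input exactly.
#'
#' @param protein Amino-acid string.
#' @return DNA string three times as long.
#' @export
back_translate <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1L]]
  codons <- CODON_TABLE[chars]
  if (anyNA(codons)) stopf("cannot back-translate residue(s): %s",
                           paste(unique(chars[is.na(codons)]), collapse = ""))
  paste(codons, collapse = "")
}

#' Insert in-frame stop codons into a coding sequence
#'
#' Replaces `n` internal codons with `TAA`, spread evenly across the middle
#' 10–90% of the sequence (stops hard against either end would be trimmed
#' off by any local alignment) — the construction used to plant pseudogenes
#' with a known number of nonsense mutations.
#'
#' @param dna Coding DNA, length a multiple of 3.
#' @param n Number of stops to insert.
#' @return List with `dna` (mutated sequence) and `codon_positions`.
#' @export
insert_stop_codons <- function(dna, n) {
  ncod <- nchar(dna) %/% 3L
  if (ncod < n + 2L) stopf("sequence too short for %d stop codons", n)
  lo <- max(2L, round(0.1 * ncod))
  hi <- min(ncod - 1L, round(0.9 * ncod))
  pos <- unique(round(seq(lo, hi, length.out = n)))
  for (p in pos) substr(dna, 3L * p - 2L, 3L * p) <- "TAA"
  list(dna = dna, codon_positions = pos)
}

# ---- configuration ----------------------------------------------------------

SIM_EVENTS <- c("duplication", "gene_loss", "terminal_domain_loss",
                "terminal_domain_gain", "fusion_fission", "repeat_change",
                "pseudogenization")

#' Configuration for the proteome evolution simulator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a species
#' tree with branch lengths, a root gene repertoire, per-lineage event
#' rates (per gene per unit branch length), a per-site substitution rate,
#' and the number of isoforms emitted per gene. Defaults describe a small
#' four-species vertebrate-like dataset with moderate divergence; see the
#' package vignette for the rationale.
#'
#' @param tree Newick string or `phylo` with branch lengths.
#' @param root_genes Optional list of root genes, each
#'   `list(gene_id =, domains = c(...))`; `NULL` draws a default repertoire
#'   of 8 genes (2–5 domains each) from the built-in domain pool.
#' @param duplication,gene_loss,terminal_domain_loss,terminal_domain_gain,fusion_fission,repeat_change,pseudogenization
#'   Event rates per gene per unit branch length (all >= 0).
#' @param substitution_rate Per-site substitution probability per unit
#'   branch length.
#' @param isoforms_per_gene Isoforms emitted per gene (>= 1); isoforms
#'   beyond the first are C-terminally truncated copies.
#' @param dialects Character vector of header dialect names, recycled over
#'   species in tip-label order.
#' @param seed Integer seed; a fixed seed makes outputs byte-identical.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree = "((sp1:0.05,sp2:0.05):0.05,(sp3:0.05,sp4:0.05):0.05);",
                       root_genes = NULL,
                       duplication = 0.05, gene_loss = 0.05,
                       terminal_domain_loss = 0.02,
                       terminal_domain_gain = 0.02,
                       fusion_fission = 0.01, repeat_change = 0.03,
                       pseudogenization = 0.05,
                       substitution_rate = 0.05,
                       isoforms_per_gene = 2L,
                       dialects = c("ensembl", "uniprot", "ncbi"),
                       seed = 1L) {
  rates <- c(duplication = duplication, gene_loss = gene_loss,
             terminal_domain_loss = terminal_domain_loss,
             terminal_domain_gain = terminal_domain_gain,
             fusion_fission = fusion_fission,
             repeat_change = repeat_change,
             pseudogenization = pseudogenization)
  if (any(rates < 0) || substitution_rate < 0)
    stopf("all rates must be >= 0")
  if (isoforms_per_gene < 1L) stopf("isoforms_per_gene must be >= 1")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stopf("tree must have branch lengths")
  structure(list(tree = tree, root_genes = root_genes, rates = rates,
                 substitution_rate = substitution_rate,
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 dialects = dialects, seed = as.integer(seed)),
            class = "sim_config")
}

default_root_genes <- function(seed) {
  pool <- c("Gla", "EGF", "Kringle", "PAN_1", "Trypsin", "FXa_inhibition",
            "VWD", "TIL", "C8", "Sushi", "Cu-oxidase", "F5_F8_type_C",
            "Transglut_N", "Transglut_core", "Transglut_C", "fn1", "fn2")
  set.seed(derive_seed(seed, 0L))
  lapply(seq_len(8L), function(i) {
    nd <- sample(2:5, 1L)
    list(gene_id = sprintf("g%02d", i),
         domains = sample(pool, nd, replace = TRUE))
  })
}

# ---- simulation core --------------------------------------------------------

# Root genes diverge each domain instance ~10% from the family prototype,
# so distinct families are separable even when their domain compositions
# overlap (the logged-ortholog separability invariant).
new_gene <- function(gene_id, family, domains) {
  seqs <- lapply(seq_along(domains), function(i)
    mutate_with_seed(domain_base_seq(domains[i]), 0.10,
                     derive_seed(sum(utf8ToInt(gene_id)) * 13L + i, 23L)))
  list(gene_id = gene_id, family = family, domains = domains,
       seqs = seqs, pseudo = FALSE, stops = 0L, pseudo_dna = NULL)
}

gene_protein <- function(g) {
  paste(unlist(g$seqs), collapse = LINKER)
}

mutate_seq <- function(s, p_site) {
  n <- nchar(s)
  k <- stats::rbinom(1L, n, min(1, p_site))
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  chars <- strsplit(s, "")[[1L]]
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

apply_event <- function(genes, gi, ev, counters, log_add, branch) {
  g <- genes[[gi]]
  detail <- ""
  if (ev == "duplication") {
    counters$dup <- counters$dup + 1L
    ng <- g
    ng$gene_id <- sprintf("%s.d%d", g$gene_id, counters$dup)
    genes[[length(genes) + 1L]] <- ng
    detail <- ng$gene_id
  } else if (ev == "gene_loss") {
    genes[[gi]] <- NULL
    detail <- "removed"
  } else if (ev == "terminal_domain_loss") {
    if (length(g$domains) > 1L) {
      side <- sample(c("N", "C"), 1L)
      i <- if (side == "N") 1L else length(g$domains)
      detail <- sprintf("%s:%s", side, g$domains[i])
      g$domains <- g$domains[-i]; g$seqs <- g$seqs[-i]
      genes[[gi]] <- g
    } else detail <- "skipped_single_domain"
  } else if (ev == "terminal_domain_gain") {
    dom <- sample(names(DOMAIN_LENGTHS), 1L)
    side <- sample(c("N", "C"), 1L)
    gained <- mutate_seq(domain_base_seq(dom), 0.10)
    if (side == "N") {
      g$domains <- c(dom, g$domains)
      g$seqs <- c(list(gained), g$seqs)
    } else {
      g$domains <- c(g$domains, dom)
      g$seqs <- c(g$seqs, list(gained))
    }
    detail <- sprintf("%s:%s", side, dom)
    genes[[gi]] <- g
  } else if (ev == "fusion_fission") {
    active <- which(!vapply(genes, `[[`, FALSE, "pseudo"))
    if (length(active) >= 2L && stats::runif(1L) < 0.5) {
      other <- sample(setdiff(active, gi), 1L)
      og <- genes[[other]]
      g$domains <- c(g$domains, og$domains)
      g$seqs <- c(g$seqs, og$seqs)
      detail <- sprintf("fusion:%s+%s", g$gene_id, og$gene_id)
      genes[[gi]] <- g
      genes[[other]] <- NULL
    } else if (length(g$domains) >= 2L) {
      cut <- sample(seq_len(length(g$domains) - 1L), 1L)
      counters$fis <- counters$fis + 1L
      g2 <- g
      g2$gene_id <- sprintf("%s.f%d", g$gene_id, counters$fis)
      g2$domains <- g$domains[-seq_len(cut)]
      g2$seqs <- g$seqs[-seq_len(cut)]
      g$domains <- g$domains[seq_len(cut)]
      g$seqs <- g$seqs[seq_len(cut)]
      detail <- sprintf("fission:%s@%d", g$gene_id, cut)
      genes[[gi]] <- g
      genes[[length(genes) + 1L]] <- g2
    } else detail <- "skipped"
  } else if (ev == "repeat_change") {
    i <- sample(seq_along(g$domains), 1L)
    runlen <- sum(g$domains == g$domains[i])
    if (runlen >= 2L && stats::runif(1L) < 0.5) {
      detail <- sprintf("contract:%s", g$domains[i])
      g$domains <- g$domains[-i]; g$seqs <- g$seqs[-i]
    } else {
      detail <- sprintf("expand:%s", g$domains[i])
      g$domains <- append(g$domains, g$domains[i], after = i)
      g$seqs <- append(g$seqs, g$seqs[i], after = i)
    }
    genes[[gi]] <- g
  } else if (ev == "pseudogenization") {
    n_stops <- sample(1:5, 1L)
    dna <- back_translate(gene_protein(g))
    g$pseudo <- TRUE
    g$stops <- n_stops
    g$pseudo_dna <- insert_stop_codons(dna, n_stops)$dna
    detail <- sprintf("stops:%d", n_stops)
    genes[[gi]] <- g
  }
  log_add(branch, g$gene_id, ev, detail)
  genes
}

evolve_branch <- function(genes, branch_len, branch, config, counters,
                          log_add) {
  rates <- config$rates
  total_rate_per_gene <- sum(rates)
  # event intensity is fixed by the repertoire size at the start of the
  # branch, so per-branch event counts are Poisson(rate * n0 * length)
  n0 <- sum(!vapply(genes, `[[`, FALSE, "pseudo"))
  t <- 0
  if (total_rate_per_gene > 0 && n0 > 0L) {
    total <- n0 * total_rate_per_gene
    repeat {
      t <- t + stats::rexp(1L, total)
      if (t > branch_len) break
      active <- which(!vapply(genes, `[[`, FALSE, "pseudo"))
      if (length(active) == 0L) break
      gi <- if (length(active) == 1L) active else sample(active, 1L)
      ev <- sample(SIM_EVENTS, 1L, prob = rates)
      genes <- apply_event(genes, gi, ev, counters, log_add, branch)
    }
  }
  p_site <- config$substitution_rate * branch_len
  if (p_site > 0) {
    for (i in seq_along(genes)) {
      if (genes[[i]]$pseudo) next
      genes[[i]]$seqs <- lapply(genes[[i]]$seqs, mutate_seq, p_site = p_site)
    }
  }
  genes
}

# ---- output writers ---------------------------------------------------------

format_header <- function(pid, gid, dialect) {
  switch(dialect,
    ensembl = sprintf("%s pep gene:%s transcript:%s.t1", pid, gid, pid),
    uniprot = sprintf("%s synthetic protein GN=%s PE=1 SV=1", pid, gid),
    ncbi    = sprintf("%s hypothetical protein [gene=%s]", pid, gid),
    sprintf("%s gene:%s", pid, gid))
}

# Emit all per-species files for one leaf's gene repertoire. Returns a list
# with the protein-id map (gene -> longest-isoform protein id) and hit/locus
# tables, so the caller can assemble the truth log.
emit_species <- function(species, genes, dialect, config, dir) {
  fasta <- character(0)
  hit_rows <- list()
  pid_map <- character(0)
  order_rows <- list()
  genomic <- character(0)
  pc <- 0L
  bp <- 1L
  for (g in genes) {
    dna <- if (g$pseudo) g$pseudo_dna else back_translate(gene_protein(g))
    genomic <- c(genomic, sprintf(">GENE_%s", g$gene_id), dna)
    order_rows[[length(order_rows) + 1L]] <- data.frame(
      species = species, scaffold = "scf1", gene_id = g$gene_id,
      start = bp, end = bp + nchar(dna) - 1L, strand = "+",
      stringsAsFactors = FALSE)
    bp <- bp + nchar(dna) - 1L + 5000L
    if (g$pseudo) next
    for (iso in seq_len(config$isoforms_per_gene)) {
      doms <- g$domains; seqs <- g$seqs
      if (iso > 1L) {
        if (length(doms) >= 2L) {
          drop <- min(iso - 1L, length(doms) - 1L)
          doms <- doms[seq_len(length(doms) - drop)]
          seqs <- seqs[seq_len(length(seqs) - drop)]
        } else {
          seqs[[1L]] <- substr(seqs[[1L]], 1L,
                               max(1L, nchar(seqs[[1L]]) - 10L * (iso - 1L)))
        }
      }
      pc <- pc + 1L
      pid <- sprintf("%s_P%04d", species, pc)
      if (iso == 1L) pid_map[g$gene_id] <- pid
      prot <- paste(unlist(seqs), collapse = LINKER)
      fasta <- c(fasta, paste0(">", format_header(pid, g$gene_id, dialect)),
                 prot)
      off <- 0L
      for (di in seq_along(doms)) {
        len <- nchar(seqs[[di]])
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          protein_id = pid, ali_start = off + 1L, ali_end = off + len,
          env_start = off + 1L, env_end = off + len,
          hmm_acc = sprintf("PF%05d.1",
                            sum(utf8ToInt(doms[di])) %% 100000L),
          domain_name = doms[di], type = "Domain", hmm_start = 1L,
          hmm_end = len, hmm_length = len, bit_score = round(1.9 * len, 1),
          e_value = signif(10^(-len / 10), 3), significance = 1L,
          clan = "", stringsAsFactors = FALSE)
        off <- off + len + nchar(LINKER)
      }
    }
  }
  writeLines(fasta, file.path(dir, paste0(species, ".proteome.fa")))
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  if (!is.null(hits))
    write_pfamscan(hits, file.path(dir, paste0(species, ".pfamscan.tsv")))
  orders <- do.call(rbind, order_rows)
  write_gene_order(orders, file.path(dir, paste0(species, ".gene_order.tsv")))
  if (length(genomic))
    writeLines(genomic, file.path(dir, paste0(species, ".genomic.fa")))
  list(pid_map = pid_map, genes = genes)
}

#' Simulate a multi-species dataset with ground truth
#'
#' Evolves the root gene repertoire along the configured species tree.
#' Events (duplication, gene loss, terminal domain loss/gain,
#' fusion/fission, repeat-count change, pseudogenization) occur with
#' exponential (Gillespie-style) waiting times at the configured per-gene
#' rates, using one RNG stream per branch keyed by (seed, branch), so any
#' branch replays identically. Substitutions are applied per site at
#' `substitution_rate * branch_length`.
#'
#' Per species the simulator writes a proteome FASTA (with isoforms, in the
#' species' header dialect), a PfamScan-style annotation table consistent
#' with every protein's true arrangement, a gene-order table, and a genomic
#' FASTA of intron-free back-translations (pseudogenes carry their logged
#' in-frame stops). A Newick copy of the tree, a `dataset.json` manifest
#' and a `truth.json` ground-truth log complete the bundle.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the truth log: list with `events`, `ortholog_pairs`,
#'   `presence` (character matrix species × root family), `pseudogenes`,
#'   and `pid_maps` (per-species gene → longest-isoform protein id).
#' @export
simulate_dataset <- function(config, dir) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- config$tree
  root_genes <- config$root_genes
  if (is.null(root_genes)) root_genes <- default_root_genes(config$seed)
  genes0 <- lapply(root_genes, function(rg)
    new_gene(rg$gene_id, rg$gene_id, rg$domains))
  families <- vapply(root_genes, `[[`, "", "gene_id")

  events <- list()
  log_add <- function(branch, gene, kind, detail)
    events[[length(events) + 1L]] <<- data.frame(
      branch = branch, gene = gene, event_kind = kind, detail = detail,
      stringsAsFactors = FALSE)
  counters <- new.env()
  counters$dup <- 0L; counters$fis <- 0L

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- function(n) tree$edge[tree$edge[, 1L] == n, 2L]
  leaf_genes <- list()
  recurse <- function(node, genes) {
    for (ch in sort(children(node))) {
      elen <- tree$edge.length[which(tree$edge[, 2L] == ch)]
      set.seed(derive_seed(config$seed, ch))
      g2 <- evolve_branch(genes, elen, branch_name(tree, ch), config,
                          counters, log_add)
      if (ch <= ntip) leaf_genes[[tree$tip.label[ch]]] <<- g2
      else recurse(ch, g2)
    }
  }
  recurse(root, genes0)

  species <- tree$tip.label
  dialects <- rep_len(config$dialects, length(species))
  names(dialects) <- species
  pid_maps <- list()
  for (sp in species) {
    res <- emit_species(sp, leaf_genes[[sp]], dialects[[sp]], config, dir)
    pid_maps[[sp]] <- res$pid_map
  }
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(list(species = species,
                            dialects = as.list(dialects)),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)

  # truth: ortholog pairs (same surviving gene lineage in both species)
  pairs <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    a <- species[i]; b <- species[j]
    ga <- leaf_genes[[a]]; gb <- leaf_genes[[b]]
    ida <- vapply(ga, `[[`, "", "gene_id")[!vapply(ga, `[[`, FALSE, "pseudo")]
    idb <- vapply(gb, `[[`, "", "gene_id")[!vapply(gb, `[[`, FALSE, "pseudo")]
    shared <- intersect(ida, idb)
    if (length(shared))
      pairs[[length(pairs) + 1L]] <- data.frame(
        species_a = a, species_b = b, gene_id = shared,
        protein_a = unname(pid_maps[[a]][shared]),
        protein_b = unname(pid_maps[[b]][shared]),
        stringsAsFactors = FALSE)
  }
  presence <- matrix("-", length(species), length(families),
                     dimnames = list(species, families))
  pseudo_rows <- list()
  for (sp in species) {
    for (g in leaf_genes[[sp]]) {
      if (g$pseudo) {
        pseudo_rows[[length(pseudo_rows) + 1L]] <- data.frame(
          species = sp, gene = g$gene_id, n_stops_inserted = g$stops,
          stringsAsFactors = FALSE)
      } else if (g$family %in% families) {
        presence[sp, g$family] <- "+"
      }
    }
  }
  truth <- list(
    events = if (length(events)) do.call(rbind, events) else
      data.frame(branch = character(), gene = character(),
                 event_kind = character(), detail = character()),
    ortholog_pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(species_a = character(), species_b = character(),
                 gene_id = character(), protein_a = character(),
                 protein_b = character()),
    presence = presence,
    pseudogenes = if (length(pseudo_rows)) do.call(rbind, pseudo_rows) else
      data.frame(species = character(), gene = character(),
                 n_stops_inserted = integer()),
    pid_maps = pid_maps)
  jsonlite::write_json(
    list(events = truth$events, ortholog_pairs = truth$ortholog_pairs,
         presence = list(species = rownames(presence),
                         family = colnames(presence),
                         states = apply(presence, 1L, paste,
                                        collapse = "")),
         pseudogenes = truth$pseudogenes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
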