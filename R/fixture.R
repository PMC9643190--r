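# Hand-authored vertebrate coagulation-cascade fixture: the published
# domain arrangements, the clade-level presence/absence/unknown matrix and
# the vertebrate clade topology, emitted in the same file formats as the
# simulator so the full pipeline can run on it.

COAG_GEFT <- c("Gla", "EGF", "FXa_inhibition", "Trypsin")

COAG_ARRANGEMENTS <- list(
  V     = c(rep("Cu-oxidase", 5L), "F5_F8_type_C"),
  VII   = c("Gla", "EGF", "Trypsin"),
  VIII  = c(rep("Cu-oxidase", 4L), "F5_F8_type_C"),
  IX    = COAG_GEFT,
  X     = COAG_GEFT,
  XI    = c(rep("PAN_1", 4L), "Trypsin"),
  XII   = c("fn2", "EGF", "fn1", "EGF", "Kringle", "Trypsin"),
  XIIIA = c("Transglut_N", "Transglut_core", "Transglut_C", "Transglut_C"),
  XIIIB = rep("Sushi", 10L),
  C     = COAG_GEFT,
  Z     = COAG_GEFT,
  S     = c("Gla", "EGF", "FXa_inhibition", "EGF_CA", "EGF_CA",
            "Laminin_G_1", "Laminin_G_2"),
  THRB  = c("Gla", "Kringle", "Kringle", "Thrombin_light", "Trypsin"),
  PLG   = c("PAN_1", rep("Kringle", 5L), "Trypsin"),
  KLKB  = c(rep("PAN_1", 4L), "Trypsin"),
  vWF   = c("VWD", "TIL", "C8", "VWD", "TIL", "C8", "VWD", "TIL", "C8",
            "VWA", "VWA", "VWA", "VWC")
)

# Arthropod hemolymph-clotting outgroup proteins: hemolectin shares exactly
# VWD, TIL and C8 with von Willebrand factor; the transglutaminase shares
# the full factor XIIIA arrangement.
COAG_OUTGROUP_ARRANGEMENTS <- list(
  HML = c("VWD", "TIL", "C8", "VWD", "TIL", "C8", "fn2"),
  TGM = c("Transglut_N", "Transglut_core", "Transglut_C", "Transglut_C")
)

# Conserved neighbourhood genes present in every vertebrate of the fixture:
# the real ccdc80/gpr161 flanks of FV, plus synthetic single-domain
# housekeeping loci interleaved between the coagulation genes so that every
# gene has flanking neighbours that survive in every species.
coag_flank_genes <- function() {
  hk <- paste0("hk", sprintf("%02d", 0:16))
  doms <- c(list(ccdc80 = c("Ldl_recept_b", "Ldl_recept_b"),
                 gpr161 = "7tm_1"),
            stats::setNames(lapply(seq_along(hk), function(i)
              paste0("Housekeep_", i)), hk))
  doms
}

# chr1 gene order of the fixture genome: coagulation genes interleaved with
# housekeeping loci; FV sits between ccdc80 and gpr161 as in ray-finned and
# cartilaginous fish genomes.
coag_gene_order_template <- function() {
  coag <- names(COAG_ARRANGEMENTS)
  rest <- setdiff(coag, "V")
  out <- c("hk00", "ccdc80", "V", "gpr161")
  for (i in seq_along(rest)) out <- c(out, sprintf("hk%02d", i), rest[i])
  c(out, "hk16")
}

COAG_CLADES <- c("jawless", "cartilaginous_fish", "ray_finned_fish",
                 "lobe_finned_fish", "amphibian", "reptile", "bird",
                 "monotreme", "marsupial", "cetacean", "placental")

COAG_TREE <- paste0(
  "(jawless,(cartilaginous_fish,(ray_finned_fish,(lobe_finned_fish,",
  "(amphibian,((reptile,bird)sauropsida,(monotreme,(marsupial,",
  "(cetacean,placental)eutheria)theria)mammalia)amniota)tetrapoda)",
  "sarcopterygii)euteleostomi)gnathostomata)vertebrata;")

# Clade x protein states (+ present, - absent, ? unknown).
coag_presence_matrix <- function() {
  prots <- c("V", "VII", "VIII", "IX", "X", "XI", "XII", "XIIIA", "XIIIB",
             "C", "Z", "S", "THRB", "PLG", "KLKB", "vWF")
  rows <- list(
    jawless            = c("?", "+", "-", "-", "+", "-", "-", "-", "-", "-", "-", "+", "+", "+", "-", "+"),
    cartilaginous_fish = c("+", "+", "+", "+", "+", "-", "-", "+", "-", "+", "+", "+", "+", "+", "-", "+"),
    ray_finned_fish    = c("+", "+", "+", "+", "+", "-", "-", "+", "+", "+", "+", "+", "+", "+", "-", "+"),
    lobe_finned_fish   = c("+", "+", "+", "+", "+", "-", "-", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    amphibian          = c("+", "+", "+", "+", "+", "-", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    reptile            = c("+", "+", "+", "+", "+", "-", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    bird               = c("+", "+", "+", "+", "+", "-", "-", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    monotreme          = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    marsupial          = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    cetacean           = c("+", "+", "+", "+", "+", "+", "-", "+", "+", "+", "+", "+", "+", "+", "-", "+"),
    placental          = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+"))
  m <- do.call(rbind, rows)
  colnames(m) <- prots
  m
}

fixture_gene_domains <- function(gene) {
  all <- c(COAG_ARRANGEMENTS, COAG_OUTGROUP_ARRANGEMENTS,
           coag_flank_genes())
  d <- all[[gene]]
  if (is.null(d)) stopf("unknown fixture gene: %s", gene)
  d
}

mutate_with_seed <- function(s, p, seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mutate_seq(s, p)
}

# Master (ancestral) per-domain sequences for one fixture gene: the family
# base sequence diverged 10% per domain instance, so paralogous proteins
# sharing an arrangement (e.g. FIX/FX/PC/PZ, FXI/PK) are clearly
# separable, while orthologs (2% further per species) stay close.
fixture_master_seqs <- function(gene) {
  doms <- fixture_gene_domains(gene)
  lapply(seq_along(doms), function(i)
    mutate_with_seed(domain_base_seq(doms[i]), 0.10,
                     derive_seed(sum(utf8ToInt(gene)) * 13L + i, 17L)))
}

fixture_species_seqs <- function(gene, species) {
  ms <- fixture_master_seqs(gene)
  lapply(seq_along(ms), function(i)
    mutate_with_seed(ms[[i]], 0.02,
                     derive_seed(sum(utf8ToInt(paste0(species, gene))) *
                                 7L + i, 29L)))
}

fixture_protein <- function(gene, species) {
  paste(unlist(fixture_species_seqs(gene, species)), collapse = LINKER)
}

emit_fixture_species <- function(species, genes, dir, genomic_entries) {
  fasta <- character(0)
  hit_rows <- list()
  order_rows <- list()
  bp <- 1L
  scaffold_of <- function(g) {
    if (species == "jawless" && g == "ccdc80") return("scafA")
    if (species == "jawless" && g == "gpr161") return("scafB")
    "chr1"
  }
  for (g in genes) {
    doms <- fixture_gene_domains(g)
    seqs <- fixture_species_seqs(g, species)
    pid <- paste0(species, "_", g)
    prot <- paste(unlist(seqs), collapse = LINKER)
    fasta <- c(fasta,
               sprintf(">%s pep gene:%s transcript:%s.t1", pid, g, pid),
               prot)
    off <- 0L
    for (di in seq_along(doms)) {
      len <- nchar(seqs[[di]])
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = pid, ali_start = off + 1L, ali_end = off + len,
        env_start = off + 1L, env_end = off + len,
        hmm_acc = sprintf("PF%05d.1", sum(utf8ToInt(doms[di])) %% 100000L),
        domain_name = doms[di], type = "Domain", hmm_start = 1L,
        hmm_end = len, hmm_length = len, bit_score = round(1.9 * len, 1),
        e_value = signif(10^(-len / 10), 3), significance = 1L, clan = "",
        stringsAsFactors = FALSE)
      off <- off + len + nchar(LINKER)
    }
    order_rows[[length(order_rows) + 1L]] <- data.frame(
      species = species, scaffold = scaffold_of(g), gene_id = g,
      start = bp, end = bp + 3L * nchar(prot) - 1L, strand = "+",
      stringsAsFactors = FALSE)
    bp <- bp + 3L * nchar(prot) - 1L + 5000L
  }
  writeLines(fasta, file.path(dir, paste0(species, ".proteome.fa")))
  write_pfamscan(do.call(rbind, hit_rows),
                 file.path(dir, paste0(species, ".pfamscan.tsv")))
  write_gene_order(do.call(rbind, order_rows),
                   file.path(dir, paste0(species, ".gene_order.tsv")))
  if (!is.null(genomic_entries))
    writeLines(genomic_entries, file.path(dir, paste0(species, ".genomic.fa")))
  invisible(NULL)
}

#' Emit the coagulation-cascade fixture dataset
#'
#' Writes a hand-authored dataset encoding the published biology of the
#' vertebrate blood-coagulation cascade: the canonical domain arrangements
#' (FIX/FX/protein C/protein Z sharing Gla–EGF–FXa_inhibition–Trypsin, FVII
#' without the FXa-inhibition domain, FXI/plasma kallikrein with four
#' tandem PAN_1 apple domains, FXII, prothrombin, plasminogen, FV/FVIII
#' multicopper-oxidase repeats, FXIIIA's transglutaminase layout, von
#' Willebrand factor), the clade-level presence matrix (with `?` for FV in
#' jawless vertebrates), the vertebrate clade topology, a pseudogenized
#' FXII copy in the cetacean genome carrying four in-frame stop codons, and
#' a split-scaffold ccdc80/gpr161 neighbourhood for FV in jawless
#' vertebrates. Conserved housekeeping loci are interleaved between the
#' coagulation genes so the flanking-gene synteny test has neighbours in
#' every species. Two arthropod outgroup proteins (hemolectin and a
#' transglutaminase) are included for homology use only.
#'
#' Gene order, loci and the sequences themselves are synthetic
#' constructions consistent with those published facts, not real genome
#' data.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `arrangements` (named list of
#'   [domain_arrangement()]s including the outgroup proteins), `presence`
#'   (clade × protein character matrix), `tree` (phylo), `pseudogenes`
#'   (data frame), `species`.
#' @export
coagulation_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  presence <- coag_presence_matrix()
  tree <- ape::read.tree(text = COAG_TREE)
  template <- coag_gene_order_template()
  flank <- names(coag_flank_genes())
  for (sp in COAG_CLADES) {
    prots <- colnames(presence)[presence[sp, ] == "+"]
    # the cetacean carries an annotated (but pseudogenized) FXII prediction
    if (sp == "cetacean") prots <- union(prots, "XII")
    genes <- template[template %in% c(flank, prots)]
    genomic <- NULL
    if (sp == "cetacean") {
      dna <- back_translate(fixture_protein("XII", "cetacean"))
      dna <- insert_stop_codons(dna, 4L)$dna
      genomic <- c(">GENE_XII", dna)
    }
    if (sp == "jawless") {
      vfrag <- substr(fixture_protein("V", "jawless"), 1L, 200L)
      genomic <- c(">GENE_V", back_translate(vfrag))
    }
    emit_fixture_species(sp, genes, dir, genomic)
  }
  emit_fixture_species("fruit_fly", names(COAG_OUTGROUP_ARRANGEMENTS), dir,
                       NULL)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  write_presence_matrix(presence, file.path(dir, "presence_truth.tsv"))
  species <- c(COAG_CLADES, "fruit_fly")
  dialects <- as.list(stats::setNames(rep("ensembl", length(species)),
                                      species))
  jsonlite::write_json(
    list(species = species, dialects = dialects,
         clade_hits = data.frame(species = "jawless", gene = "V",
                                 stringsAsFactors = FALSE)),
    file.path(dir, "dataset.json"), auto_unbox = TRUE)
  pseudo <- data.frame(species = "cetacean", gene = "XII",
                       n_stops_inserted = 4L, stringsAsFactors = FALSE)
  arr <- c(COAG_ARRANGEMENTS, COAG_OUTGROUP_ARRANGEMENTS)
  arrangements <- lapply(names(arr), function(p)
    domain_arrangement(arr[[p]], protein_id = p))
  names(arrangements) <- names(arr)
  invisible(list(arrangements = arrangements, presence = presence,
                 tree = tree, pseudogenes = pseudo, species = species,
                 dir = dir))
}
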