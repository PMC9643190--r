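null_config <- function(seed = 1L, ...)
  sim_config(duplication = 0, gene_loss = 0, terminal_domain_loss = 0,
             terminal_domain_gain = 0, fusion_fission = 0,
             repeat_change = 0, pseudogenization = 0,
             substitution_rate = 0, seed = seed, ...)

dataset_md5 <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  sums
}

test_that("the null simulation reproduces the root proteome in every species", {
  dir <- withr::local_tempdir()
  truth <- simulate_dataset(null_config(), dir)
  expect_equal(nrow(truth$events), 0L)
  seqs <- lapply(c("sp1", "sp2", "sp3", "sp4"), function(sp) {
    p <- read_proteome(file.path(dir, paste0(sp, ".proteome.fa")),
                       jsonlite::read_json(file.path(dir, "dataset.json"),
                                           simplifyVector = TRUE
                       )$dialects[[sp]], sp)
    sort(clean_isoforms(p)$sequence)
  })
  for (i in 2:4) expect_identical(seqs[[i]], seqs[[1]])
  expect_true(all(truth$presence == "+"))
})

test_that("a fixed seed reproduces the dataset byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 9L)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  m1 <- dataset_md5(d1); m2 <- dataset_md5(d2)
  expect_identical(names(m1), names(m2))
  expect_identical(unname(m1), unname(m2))
  # and a different seed gives a different proteome
  d3 <- withr::local_tempdir()
  simulate_dataset(sim_config(seed = 10L), d3)
  expect_false(identical(unname(dataset_md5(d3)), unname(m1)))
})

test_that("per-branch event counts follow the configured Poisson intensity", {
  # one root gene on a two-leaf tree with nearly all length on one branch:
  # duplications on that branch are Poisson(rate * L) because the intensity
  # is fixed by the repertoire at the branch start
  rate <- 0.25; L <- 4
  counts <- integer(100)
  for (s in seq_len(100)) {
    cfg <- sim_config(tree = sprintf("(A:%d,B:0.0001);", L),
                      root_genes = list(list(gene_id = "g1",
                                             domains = c("Gla", "Trypsin"))),
                      duplication = rate, gene_loss = 0,
                      terminal_domain_loss = 0, terminal_domain_gain = 0,
                      fusion_fission = 0, repeat_change = 0,
                      pseudogenization = 0, substitution_rate = 0,
                      isoforms_per_gene = 1L, seed = s)
    dir <- file.path(tempdir(), "poisson")
    truth <- simulate_dataset(cfg, dir)
    counts[s] <- sum(truth$events$event_kind == "duplication")
  }
  mu <- rate * L * 100
  expect_lt(abs(sum(counts) - mu), 3 * sqrt(mu))
})

test_that("annotations, gene order and truth log are consistent with the proteomes", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 23L, fusion_fission = 0)
  truth <- simulate_dataset(cfg, dir)
  ds <- jsonlite::read_json(file.path(dir, "dataset.json"),
                            simplifyVector = TRUE)
  for (sp in ds$species) {
    prot <- read_proteome(file.path(dir, paste0(sp, ".proteome.fa")),
                          ds$dialects[[sp]], sp)
    hits <- read_pfamscan(file.path(dir, paste0(sp, ".pfamscan.tsv")))
    # every hit lies inside its protein
    len <- stats::setNames(nchar(prot$sequence), prot$protein_id)
    expect_true(all(hits$env_end <= len[hits$protein_id]))
    # presence derived from the proteome equals the truth matrix
    fam <- unique(sub("\\..*$", "", prot$gene_id))
    derived <- ifelse(colnames(truth$presence) %in% fam, "+", "-")
    expect_equal(unname(truth$presence[sp, ]), derived)
  }
  # pseudogenes: genomic copy carries the logged number of stops
  if (nrow(truth$pseudogenes)) {
    for (i in seq_len(nrow(truth$pseudogenes))) {
      sp <- truth$pseudogenes$species[i]
      g <- truth$pseudogenes$gene[i]
      gen <- Biostrings::readDNAStringSet(
        file.path(dir, paste0(sp, ".genomic.fa")))
      dna <- as.character(gen[[paste0("GENE_", g)]])
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                               if.fuzzy.codon = "X"))
      n_stops <- lengths(regmatches(aa, gregexpr("\\*", aa)))
      expect_equal(n_stops, truth$pseudogenes$n_stops_inserted[i])
    }
  }
})

test_that("logged ortholog pairs are separable from non-orthologs at low divergence", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 31L, substitution_rate = 0.1,
                    duplication = 0, pseudogenization = 0, gene_loss = 0,
                    fusion_fission = 0, terminal_domain_loss = 0,
                    terminal_domain_gain = 0, repeat_change = 0)
  truth <- simulate_dataset(cfg, dir)
  ds <- jsonlite::read_json(file.path(dir, "dataset.json"),
                            simplifyVector = TRUE)
  prot <- lapply(ds$species, function(sp)
    clean_isoforms(read_proteome(file.path(dir, paste0(sp, ".proteome.fa")),
                                 ds$dialects[[sp]], sp)))
  names(prot) <- ds$species
  ident <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    mean(strsplit(substr(a, 1, n), "")[[1]] ==
           strsplit(substr(b, 1, n), "")[[1]])
  }
  op <- truth$ortholog_pairs
  expect_gt(nrow(op), 0L)
  for (i in seq_len(min(nrow(op), 20L))) {
    pa <- prot[[op$species_a[i]]]
    pb <- prot[[op$species_b[i]]]
    sa <- pa$sequence[pa$protein_id == op$protein_a[i]]
    sb <- pb$sequence[pb$protein_id == op$protein_b[i]]
    expect_gte(ident(sa, sb), 0.8)
    # identity to a different family's protein is far lower
    other <- pb[pb$gene_id != op$gene_id[i], ]
    if (nrow(other)) expect_lt(ident(sa, other$sequence[1]), 0.6)
  }
})

test_that("negative rates are rejected", {
  expect_error(sim_config(duplication = -1), ">= 0")
  expect_error(sim_config(isoforms_per_gene = 0), ">= 1")
})
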