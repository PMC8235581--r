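test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 31L, n_genomes = 2L, genome_length_bp = 30000L,
                    gene_count = 25L, feature_plan = small_plan())
  d1 <- simulate_genome_set(cfg)
  d2 <- simulate_genome_set(cfg)
  expect_identical(lapply(d1$genomes, function(g) as.character(g$replicons)),
                   lapply(d2$genomes, function(g) as.character(g$replicons)))
  expect_identical(d1$features, d2$features)
  expect_identical(d1$truth$genes, d2$truth$genes)
})

test_that("realized GC tracks the target on a gene-light 100-kb genome", {
  anc <- simulate_ancestor(sim_config(seed = 32L, n_genomes = 1L,
                                      genome_length_bp = 100000L,
                                      gene_count = 40L, gc_target = 0.55,
                                      feature_plan = list()))
  fr <- Biostrings::letterFrequency(anc$genome$replicons, c("G", "C"))
  gc <- sum(fr) / sum(Biostrings::width(anc$genome$replicons))
  expect_lt(abs(gc - 0.55), 0.01)
})

test_that("planted cytochromes carry exactly the requested motif count", {
  for (k in c(0L, 1L, 4L, 9L)) {
    p <- make_cytochrome_protein(k)
    expect_equal(scan_heme_motifs(p)$motif_count, k)
    expect_equal(scan_heme_motifs(p, "literal")$motif_count, k)
  }
})

test_that("evolution at p = 0 is the identity and realized mismatch matches p", {
  anc <- flat_ancestor()
  ev0 <- evolve_genome(anc$genome, anc$features, p = 0, seed = 1L, genome_id = "C")
  expect_identical(as.character(ev0$genome$replicons),
                   stats::setNames(as.character(anc$genome$replicons),
                                   names(anc$genome$replicons)))
  ev <- evolve_genome(anc$genome, anc$features, p = 0.10, seed = 2L, genome_id = "C")
  a <- strsplit(as.character(anc$genome$replicons[[1]]), "")[[1]]
  b <- strsplit(as.character(ev$genome$replicons[[1]]), "")[[1]]
  expect_lt(abs(mean(a != b) - 0.10), 0.005)
})

test_that("pairwise divergence of two siblings follows the branch composition", {
  # expected mismatch between children at rates pa, pb is
  # pa + pb - (4/3) pa pb (both mutate and coincide with prob 1/3)
  anc <- flat_ancestor(seed = 502L)
  pa <- 0.10; pb <- 0.20
  ca <- evolve_genome(anc$genome, anc$features, p = pa, seed = 11L, genome_id = "A")
  cb <- evolve_genome(anc$genome, anc$features, p = pb, seed = 12L, genome_id = "B")
  a <- strsplit(as.character(ca$genome$replicons[[1]]), "")[[1]]
  b <- strsplit(as.character(cb$genome$replicons[[1]]), "")[[1]]
  expected <- pa + pb - (4 / 3) * pa * pb
  expect_lt(abs(mean(a != b) - expected), 0.01)
  tr <- simulate_genome_set(sim_config(seed = 33L, n_genomes = 2L,
                                       genome_length_bp = 30000L,
                                       gene_count = 25L,
                                       substitution_rate = 0.05,
                                       feature_plan = small_plan()))$truth
  expect_equal(tr$expected_identity["G1", "G2"], 100 * (1 - 0.05))
  expect_identical(tr$expected_identity, t(tr$expected_identity))
})

test_that("indels stay out of coding regions and leave annotations valid", {
  anc <- flat_ancestor(seed = 503L, len = 20000L)
  ev <- evolve_genome(anc$genome, anc$features, p = 0.02, indel_rate = 0.002,
                      seed = 3L, genome_id = "C")
  prot_anc <- derive_proteome(anc$genome, anc$features)
  prot_ev <- derive_proteome(ev$genome, ev$features)
  expect_equal(nrow(prot_ev), nrow(prot_anc))
  expect_false(any(prot_ev$disrupted))
  # genome length changed (indels happened) but every feature still parses
  expect_false(sum(Biostrings::width(ev$genome$replicons)) ==
                 sum(Biostrings::width(anc$genome$replicons)))
})

test_that("emitted datasets round-trip through the reader with a complete truth table", {
  ds <- small_dataset()
  out <- file.path(tempdir(), "genosig_emit_test")
  paths <- emit_dataset(ds, out)
  expect_true(all(file.exists(paths)))
  expect_length(paths, 2L * length(ds$genomes) + 2L)
  back <- read_annotated_genome(paths[["G2.fna"]], paths[["G2.gff3"]],
                                genome_id = "G2")
  expect_identical(as.character(back$genome$replicons),
                   as.character(ds$genomes$G2$replicons))
  tj <- jsonlite::read_json(paths[["truth.json"]], simplifyVector = TRUE)
  ids <- names(ds$genomes)
  expect_true(all(ids %in% names(tj$expected_identity)))
  expect_equal(nrow(tj$expected_identity), length(ids))
})

test_that("every planted gene appears exactly once per target genome", {
  ds <- small_dataset()
  tg <- ds$truth$genes
  counts <- table(tg$family_id, tg$genome_id)
  expect_true(all(counts <= 1L))
  planted2 <- tg$family_id[tg$genome_id == "G1" & grepl("k=7", tg$param)]
  expect_false(any(tg$family_id == planted2 & tg$genome_id == "G3"))
})
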