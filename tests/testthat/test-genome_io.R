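test_that("GFF3 coordinates convert to 0-based half-open and attributes parse", {
  fa <- tempfile(fileext = ".fna")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(">repl1", paste(rep("ACGTACGTAC", 10), collapse = "")), fa)
  writeLines(c("##gff-version 3",
               "repl1\ttest\tCDS\t1\t30\t.\t+\t0\tID=f1;locus_tag=AOP6_0001;product=widget"),
             gff)
  ag <- read_annotated_genome(fa, gff, genome_id = "T1")
  expect_equal(ag$features$start, 0L)
  expect_equal(ag$features$end, 30L)
  expect_equal(ag$features$locus_tag, "AOP6_0001")
  expect_equal(ag$features$kind, "CDS")
})

test_that("out-of-bounds features and duplicate locus tags are hard errors", {
  fa <- tempfile(fileext = ".fna")
  writeLines(c(">r1", "ACGTACGTAC"), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "r1\tt\tCDS\t5\t40\t.\t+\t0\tID=bad1;locus_tag=L1"), gff)
  expect_error(read_annotated_genome(fa, gff), "bad1")
  writeLines(c("##gff-version 3",
               "r1\tt\tCDS\t1\t3\t.\t+\t0\tID=a;locus_tag=L1",
               "r1\tt\tCDS\t4\t6\t.\t+\t0\tID=b;locus_tag=L1"), gff)
  expect_error(read_annotated_genome(fa, gff), "locus_tag")
})

test_that("translation follows table 11, strand and disruption rules", {
  g <- genome_record("T", c(chr = "ATGGCCTAA"))
  f <- make_features(1, "x", gene_len = 9L)
  expect_equal(derive_proteome(g, f)$sequence, "MA")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGGCCTAA")))
  g2 <- genome_record("T", stats::setNames(Biostrings::DNAStringSet(rc), "chr"))
  f2 <- f; f2$strand <- "-"
  expect_equal(derive_proteome(g2, f2)$sequence, "MA")

  g3 <- genome_record("T", c(chr = "ATGTAAGCC"))
  expect_true(derive_proteome(g3, f)$disrupted)

  g4 <- genome_record("T", c(chr = "ATGGCCGGTAA"))
  f4 <- f; f4$end <- 11L
  expect_warning(p4 <- derive_proteome(g4, f4), "divisible")
  expect_true(p4$partial)
  expect_equal(p4$sequence, "MAG")
})

test_that("proteome is invariant under replicon reverse complement with flipped strands", {
  ds <- small_dataset()
  g <- ds$genomes$G1
  f <- ds$features$G1
  p1 <- sort(derive_proteome(g, f)$sequence)
  L <- Biostrings::width(g$replicons)[1]
  grc <- genome_record("G1rc", stats::setNames(
    Biostrings::reverseComplement(g$replicons), names(g$replicons)))
  frc <- f
  frc$start <- L - f$end
  frc$end <- L - f$start
  frc$strand <- ifelse(f$strand == "+", "-", "+")
  p2 <- sort(derive_proteome(grc, frc)$sequence)
  expect_identical(p1, p2)
})

test_that("genome stats follow the GC conventions", {
  g <- genome_record("T", c(chr = "ATGC"))
  s <- genome_stats(g, empty_features_df())
  expect_equal(s$gc_percent, 50.0)
  expect_equal(s$length_bp, 4L)

  g2 <- genome_record("T", c(chr = "AANN"))
  expect_equal(genome_stats(g2, empty_features_df())$gc_percent, 0.0)

  g3 <- genome_record("T", c(chr = "NNNN"))
  expect_true(is.na(genome_stats(g3, empty_features_df())$gc_percent))

  # invariance under replicon permutation and complementation
  g4 <- genome_record("T", c(a = "GGGAT", b = "CCTA"))
  g5 <- genome_record("T", c(b = "CCTA", a = "GGGAT"))
  expect_equal(genome_stats(g4, empty_features_df())$gc_percent,
               genome_stats(g5, empty_features_df())$gc_percent)
  comp <- chartr("ACGT", "TGCA", c(a = "GGGAT", b = "CCTA"))
  g6 <- genome_record("T", comp)
  expect_equal(genome_stats(g4, empty_features_df())$gc_percent,
               genome_stats(g6, empty_features_df())$gc_percent)
})

test_that("write + read round-trips sequences and coordinates exactly", {
  ds <- small_dataset()
  fa <- tempfile(fileext = ".fna")
  gff <- tempfile(fileext = ".gff3")
  write_annotated_genome(ds$genomes$G2, ds$features$G2, fa, gff)
  back <- read_annotated_genome(fa, gff, genome_id = "G2")
  expect_identical(as.character(back$genome$replicons),
                   as.character(ds$genomes$G2$replicons))
  expect_equal(back$features$start, ds$features$G2$start)
  expect_equal(back$features$end, ds$features$G2$end)
  expect_equal(back$features$locus_tag, ds$features$G2$locus_tag)
  expect_equal(back$features$product, ds$features$G2$product)
})

test_that("the TSV feature-table dialect is accepted", {
  fa <- tempfile(fileext = ".fna")
  writeLines(c(">c1", paste(rep("ACGT", 30), collapse = ""))[1:2], fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines("c1\t1\t30\t+\tCDS\thypothetical protein\tL_0001", tsv)
  ag <- read_annotated_genome(fa, tsv, genome_id = "T")
  expect_equal(ag$features$start, 0L)
  expect_equal(ag$features$end, 30L)
  expect_equal(ag$features$kind, "CDS")
})
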