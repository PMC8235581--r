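two_tiny_proteomes <- function(seqsA, seqsB) {
  mk <- function(g, seqs) data.frame(
    protein_id = paste(g, names(seqs), sep = "|"), locus_tag = names(seqs),
    genome_id = g, sequence = unname(seqs), disrupted = FALSE, partial = FALSE,
    stringsAsFactors = FALSE)
  list(A = mk("A", seqsA), B = mk("B", seqsB))
}

test_that("identical proteins hit at identity 100 and coverage 1", {
  set.seed(1)
  s <- random_aa(100)
  pr <- two_tiny_proteomes(c(p1 = s), c(q1 = s))
  h <- all_vs_all(pr)
  expect_equal(nrow(h), 2L)
  expect_equal(h$identity, c(100, 100))
  expect_equal(h$coverage, c(1, 1))
})

test_that("proteins sharing no 5-mer produce no hit", {
  pr <- two_tiny_proteomes(c(p1 = strrep("AC", 50)), c(q1 = strrep("WY", 50)))
  expect_equal(nrow(all_vs_all(pr)), 0L)
})

test_that("the k-mer prefilter loses no hit relative to exhaustive alignment", {
  set.seed(42)
  seqsA <- stats::setNames(replicate(10, random_aa(200)), sprintf("a%02d", 1:10))
  # relatives of the A proteins plus unrelated sequences
  seqsB <- c(vapply(seqsA[1:5], evolve_protein_sequence, character(1), p = 0.1),
             stats::setNames(replicate(5, random_aa(200)), sprintf("b%02d", 6:10)))
  names(seqsB) <- sprintf("b%02d", 1:10)
  pr <- two_tiny_proteomes(seqsA, seqsB)
  with_filter <- all_vs_all(pr, kmer_prefilter_k = 5L)
  exhaustive <- all_vs_all(pr, kmer_prefilter_k = 0L)
  key <- function(h) paste(h$query_id, h$subject_id)
  expect_setequal(key(with_filter), key(exhaustive))
  m <- match(key(with_filter), key(exhaustive))
  expect_equal(with_filter$identity, exhaustive$identity[m])
  expect_equal(with_filter$score, exhaustive$score[m])
})

test_that("reciprocal best hits require mutual best and break ties deterministically", {
  set.seed(7)
  s <- random_aa(120)
  # B holds two identical copies of s: tie broken by lexicographic subject
  pr <- two_tiny_proteomes(c(p1 = s), c(q2 = s, q1 = s))
  h <- all_vs_all(pr)
  r <- build_rbh(h, "A", "B")
  expect_equal(nrow(r), 1L)
  expect_equal(r$gene_b, "B|q1")
  # shuffled input order gives the same pair
  r2 <- build_rbh(h[rev(seq_len(nrow(h))), ], "A", "B")
  expect_equal(r2$gene_b, "B|q1")

  # non-reciprocal: p2's best is q1, but q1's best is p1
  s2 <- evolve_protein_sequence(s, 0.15, seed = 5)
  pr3 <- two_tiny_proteomes(c(p1 = s, p2 = s2), c(q1 = s))
  h3 <- all_vs_all(pr3)
  r3 <- build_rbh(h3, "A", "B")
  expect_equal(r3$gene_a, "A|p1")
  expect_equal(nrow(r3), 1L)
})

test_that("OG clustering matches a union-find oracle and is order-invariant", {
  hits <- small_hits()
  rbh <- small_rbh()
  prot <- small_proteomes()
  ogset <- cluster_ogs(rbh, hits, prot)

  # oracle: same edge list, independent union-find implementation
  inter <- hits[hits$query_genome != hits$subject_genome, ]
  best_inter <- tapply(inter$score, inter$query_id, max)
  within <- hits[hits$query_genome == hits$subject_genome, ]
  thr <- best_inter[within$query_id]
  within <- within[is.na(thr) | within$score >= thr, ]
  ea <- c(rbh$gene_a, within$query_id)
  eb <- c(rbh$gene_b, within$subject_id)
  nodes <- sort(unlist(lapply(prot, function(p)
    p$protein_id[!p$disrupted & nzchar(p$sequence)])))
  comps <- uf_components(nodes, ea, eb)
  comps <- comps[lengths(comps) >= 2L]
  oracle_sets <- sort(vapply(comps, function(v) paste(sort(v), collapse = ","),
                             character(1)))
  got_sets <- sort(vapply(ogset$og, function(v) paste(sort(v), collapse = ","),
                          character(1)))
  expect_identical(unname(got_sets), unname(oracle_sets))

  # genome order invariance
  ogset_r <- cluster_ogs(rbh, hits, rev(prot))
  expect_identical(ogset$og, ogset_r$og)
})

test_that("OG accounting satisfies the partition identity and singleton behavior", {
  ogset <- small_ogset()
  m <- og_matrices(ogset)
  expect_equal(sum(m$sharing$n_ogs), length(ogset$og))
  n_in_ogs <- sum(!is.na(ogset$membership$og_id))
  expect_equal(m$fraction_assigned, round(100 * n_in_ogs / ogset$n_genes, 1))
  expect_equal(sum(lengths(ogset$og)) +
                 sum(is.na(ogset$membership$og_id)), ogset$n_genes)
})

test_that("AAI is 100 for identical proteomes regardless of gene order", {
  set.seed(9)
  seqs <- stats::setNames(replicate(8, random_aa(150)), sprintf("g%d", 1:8))
  pr <- two_tiny_proteomes(seqs, seqs[sample(names(seqs))])
  h <- all_vs_all(pr)
  r <- build_rbh_all(h)
  aai <- compute_aai(r)
  expect_equal(aai$matrix["A", "B"], 100.0)
  expect_equal(aai$table$n_pairs, 8L)
})

test_that("AAI decreases monotonically with proteome divergence", {
  set.seed(10)
  base <- stats::setNames(replicate(12, random_aa(150)), sprintf("g%d", 1:12))
  aais <- vapply(c(0.02, 0.05, 0.10, 0.20), function(p) {
    mut <- vapply(base, evolve_protein_sequence, character(1), p = p)
    pr <- two_tiny_proteomes(base, mut)
    compute_aai(build_rbh_all(all_vs_all(pr)))$matrix["A", "B"]
  }, numeric(1))
  expect_true(all(diff(aais) < 0))
})

test_that("planted families recover their OGs at p <= 0.1", {
  ds <- small_dataset()
  ogset <- small_ogset()
  tg <- ds$truth$genes
  tg$protein_id <- paste(tg$genome_id, tg$locus_tag, sep = "|")
  og_of <- stats::setNames(ogset$membership$og_id, ogset$membership$protein_id)
  tg$og <- og_of[tg$protein_id]
  agree <- vapply(split(tg, tg$family_id), function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    tb <- table(d$og, useNA = "no")
    if (!length(tb)) return(0)
    max(tb) / nrow(d)
  }, numeric(1))
  expect_gte(mean(agree, na.rm = TRUE), 0.99)
})
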