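toy_supermatrix <- function(rows) {
  structure(list(taxa = names(rows), alignment = rows,
                 partition = data.frame(og_id = "g1", start = 0L,
                                        end = nchar(rows[1]),
                                        stringsAsFactors = FALSE)),
            class = "Supermatrix")
}

test_that("single-copy selection excludes duplicated and missing families", {
  ogset <- small_ogset()
  mats <- og_matrices(ogset)
  sc <- select_single_copy(ogset)
  expect_true(all(apply(mats$counts[sc, , drop = FALSE], 1, function(r)
    all(r == 1L))))
  not_single <- rownames(mats$counts)[apply(mats$counts, 1, function(r)
    any(r != 1L))]
  expect_length(intersect(sc, not_single), 0L)
})

test_that("gap-free genes concatenate with the expected width and partition map", {
  set.seed(21)
  g1 <- random_aa(100); g2 <- random_aa(50)
  prot <- list(
    A = data.frame(protein_id = c("A|1", "A|2"), locus_tag = c("1", "2"),
                   genome_id = "A", sequence = c(g1, g2), disrupted = FALSE,
                   partial = FALSE, stringsAsFactors = FALSE),
    B = data.frame(protein_id = c("B|1", "B|2"), locus_tag = c("1", "2"),
                   genome_id = "B", sequence = c(g1, g2), disrupted = FALSE,
                   partial = FALSE, stringsAsFactors = FALSE),
    C = data.frame(protein_id = c("C|1", "C|2"), locus_tag = c("1", "2"),
                   genome_id = "C", sequence = c(g1, g2), disrupted = FALSE,
                   partial = FALSE, stringsAsFactors = FALSE))
  ogset <- structure(list(
    membership = data.frame(
      protein_id = c("A|1", "B|1", "C|1", "A|2", "B|2", "C|2"),
      genome_id = rep(c("A", "B", "C"), 2),
      og_id = rep(c("OG1", "OG2"), each = 3), stringsAsFactors = FALSE),
    og = list(OG1 = c("A|1", "B|1", "C|1"), OG2 = c("A|2", "B|2", "C|2")),
    genomes = c("A", "B", "C"), n_genes = 6L), class = "OrthologousGroupSet")
  sm <- build_supermatrix(c("OG1", "OG2"), ogset, prot)
  expect_equal(nchar(sm$alignment[["A"]]), 150L)
  expect_false(any(grepl("-", sm$alignment)))
  expect_equal(sm$partition$start, c(0L, 100L))
  expect_equal(sm$partition$end, c(100L, 150L))
})

test_that("a planted insertion aligns as a gap block in the other taxa", {
  set.seed(22)
  base <- random_aa(60)
  ins <- paste0(substr(base, 1, 30), "WWW", substr(base, 31, 60))
  seqs <- c(A = base, B = base, C = base, D = ins)
  aln <- genosig:::progressive_align(seqs)
  expect_equal(unique(nchar(aln)), 63L)
  expect_equal(aln[["D"]], ins)
  gap_cols <- gregexpr("-", aln[["A"]])[[1]]
  expect_length(gap_cols, 3L)
  expect_equal(diff(as.integer(gap_cols)), c(1L, 1L))
  expect_identical(aln[["A"]], aln[["B"]])
})

test_that("distances follow pairwise deletion and the Poisson correction", {
  m <- rbind(A = strsplit("AAAA", "")[[1]], B = strsplit("AAAT", "")[[1]])
  expect_equal(distance_matrix(m, "p-distance")["A", "B"], 0.25)
  expect_equal(distance_matrix(m, "poisson")["A", "B"], -log(0.75))
  m2 <- rbind(A = strsplit("AA-A", "")[[1]], B = strsplit("AAAA", "")[[1]])
  expect_equal(distance_matrix(m2, "p-distance")["A", "B"], 0)
  m3 <- rbind(A = c("A", "A"), B = c("A", "A"))
  expect_equal(distance_matrix(m3)["A", "B"], 0)
  m4 <- rbind(A = c("-", "A"), B = c("A", "-"))
  expect_error(distance_matrix(m4), "comparable")
})

test_that("neighbor joining solves the 3-taxon system exactly", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("neighbor joining recovers 4-taxon additive topologies", {
  # additive distances on topology ((A,B),(C,D)) with internal branch 2
  bl <- c(A = 1, B = 3, C = 2, D = 4); int <- 2
  D <- matrix(0, 4, 4, dimnames = list(names(bl), names(bl)))
  D["A", "B"] <- D["B", "A"] <- bl["A"] + bl["B"]
  D["C", "D"] <- D["D", "C"] <- bl["C"] + bl["D"]
  for (x in c("A", "B")) for (y in c("C", "D"))
    D[x, y] <- D[y, x] <- bl[x] + bl[y] + int
  tr <- nj_tree(D)
  # the generating split is the only internal bipartition
  parts <- ape::prop.part(tr)
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # recomputed path lengths reproduce the additive matrix
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]),
               unname(D))
})

test_that("non-symmetric distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(D), "symmetric")
})

test_that("bootstrap with one replicate yields supports of 0 or 1 and duplicated columns keep the topology", {
  set.seed(23)
  root <- random_aa(200)
  a1 <- evolve_protein_sequence(root, 0.05); a2 <- evolve_protein_sequence(root, 0.05)
  rows <- c(A = evolve_protein_sequence(a1, 0.05),
            B = evolve_protein_sequence(a1, 0.05),
            C = evolve_protein_sequence(a2, 0.05),
            D = evolve_protein_sequence(a2, 0.05),
            E = evolve_protein_sequence(root, 0.05))
  sm <- toy_supermatrix(rows)
  bs1 <- bootstrap_support(sm, n_reps = 1L, seed = 4L)
  expect_true(all(as.numeric(bs1$node.label) %in% c(0, 1)))
  # duplicating every column leaves the full-data topology unchanged
  dup <- toy_supermatrix(vapply(rows, function(s) paste0(s, s), character(1)))
  t1 <- nj_tree(distance_matrix(sm))
  t2 <- nj_tree(distance_matrix(dup))
  expect_equal(ape::dist.topo(t1, t2)[1], 0)
})
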