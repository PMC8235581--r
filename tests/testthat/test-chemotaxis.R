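test_that("product keywords map to chemotaxis gene kinds", {
  f <- make_features(5, c("methyl-accepting chemotaxis protein",
                          "chemotaxis response regulator CheY",
                          "CheA-CheY fusion protein",
                          "purine-binding chemotaxis protein CheW",
                          "hypothetical protein"))
  cat <- catalog_che_genes(f)
  expect_equal(nrow(cat), 4L)
  expect_equal(cat$kind, c("mcp", "cheY", "cheAY", "cheW"))
  expect_true(all(cat$evidence == "annotation keyword"))
})

test_that("user tables override keywords and conflicts are errors", {
  f <- make_features(2, c("chemotaxis protein CheA", "hypothetical protein"))
  ut <- data.frame(locus_tag = c("g0001", "g0002"), kind = c("cheB", "mcp"),
                   stringsAsFactors = FALSE)
  cat <- catalog_che_genes(f, ut)
  expect_equal(cat$kind[cat$locus_tag == "g0001"], "cheB")
  expect_equal(cat$evidence[cat$locus_tag == "g0002"], "user table")
  bad <- data.frame(locus_tag = c("g0001", "g0001"), kind = c("cheA", "cheB"),
                    stringsAsFactors = FALSE)
  expect_error(catalog_che_genes(f, bad), "conflict")
})

test_that("operon calling follows the gap and strand rules", {
  f <- make_features(2, "x", gap = 50L)
  expect_equal(nrow(call_operons(f)), 1L)
  f2 <- make_features(2, "x", gap = 500L)
  expect_equal(nrow(call_operons(f2)), 2L)
  f3 <- make_features(2, "x", gap = 50L, strand = c("+", "-"))
  expect_equal(nrow(call_operons(f3)), 2L)
})

test_that("cluster windows split on more than max_intervening non-che genes", {
  prods <- c(rep("chemotaxis protein CheA", 3), rep("hypothetical protein", 3),
             rep("chemotaxis protein CheW", 3))
  f <- make_features(9, prods)
  cat <- catalog_che_genes(f)
  det <- detect_che_clusters(cat, f, max_intervening = 2L, min_che = 3L)
  expect_equal(nrow(det$clusters), 2L)
  det2 <- detect_che_clusters(cat, f, max_intervening = 3L, min_che = 3L)
  expect_equal(nrow(det2$clusters), 1L)
  expect_equal(det2$clusters$n_che, 6L)
})

test_that("MCP heptad classes are read off the planted cytoplasmic tail", {
  expect_equal(classify_mcp(make_mcp_protein(40L))$heptad_count, 40L)
  expect_equal(classify_mcp(make_mcp_protein(40L))$class, 40L)
  expect_equal(classify_mcp(make_mcp_protein(24L))$heptad_count, 24L)
  expect_equal(classify_mcp(make_mcp_protein(24L))$class, 24L)
  short <- classify_mcp("MKLLV")
  expect_equal(short$flag, "too_short")
  no_tm <- classify_mcp(paste(rep("DEKR", 50), collapse = ""))
  expect_equal(no_tm$flag, "no_tm_helix")
  expect_true(is.na(no_tm$class))
})

test_that("cluster typing follows the rule cascade", {
  expect_equal(type_cluster(c("cheAY", "cheW", "mcp")), "FrzLike")
  expect_equal(type_cluster(c("cheA", "cheC", "cheD", "cheW", "cheY", "mcp"),
                            mcp_classes = 44L), "DifLike")
  expect_equal(type_cluster(c("cheA", "cheB", "cheR", "cheW")), "BetaGroup")
  expect_equal(type_cluster(c("cheA", "cheB", "cheR", "cheW", "cheC", "cheD",
                              "cheX")), "BetaCDX")
  expect_equal(type_cluster(c("cheA", "cheB", "cheR", "cheW", "mcp", "mcp"),
                            mcp_classes = c(36L, 36L), n_interleaved = 1L),
               "EcoliLikeType2")
  expect_equal(type_cluster(c("cheY")), "Unclassified")
  # order of members must not matter
  expect_equal(type_cluster(rev(c("cheA", "cheB", "cheR", "cheW", "cheC",
                                  "cheD", "cheX"))), "BetaCDX")
})

test_that("the full chemotaxis map recovers all planted clusters and classes", {
  rg <- rich_genome()
  cm <- map_chemotaxis(rg$features, rg$proteome)
  tg <- rg$truth$genes
  expect_setequal(cm$clusters$type,
                  c("FrzLike", "DifLike", "BetaGroup", "BetaCDX",
                    "EcoliLikeType2"))
  expect_equal(nrow(cm$clusters), 5L)
  # catalog equals truth: every che-role gene and no other
  truth_che <- tg$locus_tag[tg$role %in%
                              c("cheA", "cheAY", "cheB", "cheC", "cheD",
                                "cheR", "cheV", "cheW", "cheX", "cheY", "mcp")]
  expect_setequal(cm$catalog$locus_tag, truth_che)
  kinds_truth <- tg$role[match(cm$catalog$locus_tag, tg$locus_tag)]
  expect_identical(cm$catalog$kind, kinds_truth)
  # every MCP classifies to its planted class
  mcp_truth <- tg[tg$role == "mcp", ]
  planted_H <- as.integer(sub("H=(\\d+).*", "\\1", mcp_truth$param))
  got <- cm$mcp_classes$class[match(mcp_truth$locus_tag, cm$mcp_classes$locus_tag)]
  expect_identical(got, planted_H)
  # dispersed receptors are the ones planted outside operons
  disp_truth <- mcp_truth$locus_tag[is.na(mcp_truth$cluster_id)]
  expect_setequal(cm$dispersed_mcp, disp_truth)
})

test_that("flagellar census distinguishes a complete cluster from scatter", {
  rg <- rich_genome()
  fc <- flagellar_census(rg$features)
  expect_true(fc$complete)
  expect_equal(fc$n_flagellar_genes, 30L)
  expect_equal(fc$largest_locus, 30L)
  # scattered singletons: 10 flagellar genes with 3 intervening others
  prods <- rep(c("flagellar hook protein FlgE", rep("hypothetical protein", 3)), 10)
  f <- make_features(length(prods), prods)
  fc2 <- flagellar_census(f)
  expect_false(fc2$complete)
  expect_equal(fc2$n_loci, 10L)
  f0 <- make_features(5, "hypothetical protein")
  fc0 <- flagellar_census(f0)
  expect_false(fc0$complete)
  expect_equal(fc0$n_flagellar_genes, 0L)
})
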