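# Bray-Curtis clustering of signature matrices and the end-to-end
# pipeline orchestrator.

#' Bray-Curtis dissimilarity of two count vectors
#'
#' `d = sum(|u - v|) / sum(u + v)`; the similarity the clustering is
#' based on is `1 - d`.
#'
#' @param u,v Nonnegative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors differ in length")
  if (any(u < 0) || any(v < 0)) stopf("counts must be nonnegative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stopf("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(u - v)) / tot
}

bray_curtis_matrix <- function(mat, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (axis == "rows") mat <- t(mat)
  labs <- colnames(mat)
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    if (sum(mat[, i]) + sum(mat[, j]) == 0)
      stopf("Bray-Curtis undefined for pair %s / %s (all-zero)", labs[i], labs[j])
    d[i, j] <- d[j, i] <- bray_curtis(mat[, i], mat[, j])
  }
  d
}

#' Hierarchical clustering of a signature matrix
#'
#' Agglomerative clustering on pairwise Bray-Curtis dissimilarities;
#' average linkage (UPGMA) by default. Items are pre-sorted by label so
#' ties resolve deterministically.
#'
#' @param matrix Nonnegative count matrix (features x genomes).
#' @param axis Cluster `"columns"` (genomes, default) or `"rows"`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An [stats::hclust] object with a `leaf_order` attribute.
#' @export
hierarchical_cluster <- function(matrix, axis = c("columns", "rows"),
                                 linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  if (axis == "rows") matrix <- t(matrix)
  if (ncol(matrix) < 2L) stopf("need >= 2 items to cluster")
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  d <- bray_curtis_matrix(matrix, "columns")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  attr(hc, "leaf_order") <- hc$labels[hc$order]
  hc
}

write_matrix_tsv <- function(mat, path, row_label = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative-genomics pipeline
#'
#' Executes genome reading (or simulation), orthology, ANI/AAI,
#' phylogenomics, cytochrome/chemotaxis/mobilome profiling and
#' Bray-Curtis clustering, writing every section as TSV/Newick plus one
#' JSON index. Stage toggles skip sections (marked `"skipped"` in the
#' index); all randomness is governed by `seed`.
#'
#' @param genomes Named list of `GenomeRecord`s, or `NULL` to simulate.
#' @param features_list Named list of feature data frames (matching
#'   `genomes`).
#' @param sim A [sim_config()] used when `genomes` is `NULL`.
#' @param out_dir Output directory.
#' @param seed Master seed (bootstrap resampling).
#' @param stages Named logical toggles: `ani, aai, phylogenomics,
#'   cytochromes, chemotaxis, mobilome, clustering`.
#' @param is_library IS reference library; defaults to the packaged
#'   synthetic family seeds ([is_reference_library()]).
#' @param bootstrap_reps Bootstrap replicates for the tree stage.
#' @param heme_mode Heme-motif pattern mode.
#' @return A `ReportBundle` list (invisibly); files under `out_dir`.
#' @export
run_pipeline <- function(genomes = NULL, features_list = NULL, sim = NULL,
                         out_dir = tempfile("genosig_"), seed = 1L,
                         stages = list(), is_library = NULL,
                         bootstrap_reps = 100L, heme_mode = "canonical") {
  st <- utils::modifyList(list(ani = TRUE, aai = TRUE, phylogenomics = TRUE,
                               cytochromes = TRUE, chemotaxis = TRUE,
                               mobilome = TRUE, clustering = TRUE), stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(parameters = list(seed = seed, bootstrap_reps = bootstrap_reps,
                                  heme_mode = heme_mode,
                                  package_version = as.character(
                                    utils::packageVersion("genosig"))),
                sections = list())
  mark <- function(name, status, files = NULL)
    index$sections[[name]] <<- list(status = status, files = as.list(files))

  truth <- NULL
  if (is.null(genomes)) {
    if (is.null(sim)) stopf("provide genomes+features_list or a sim config")
    ds <- simulate_genome_set(sim)
    genomes <- ds$genomes; features_list <- ds$features; truth <- ds$truth
    emit_dataset(ds, file.path(out_dir, "simulated"))
    mark("simulation", "done", file.path(out_dir, "simulated"))
  }
  ids <- names(genomes)

  stats_df <- do.call(rbind, lapply(ids, function(g) {
    s <- genome_stats(genomes[[g]], features_list[[g]])
    data.frame(genome_id = g, length_bp = s$length_bp, gc_percent = s$gc_percent,
               cds_count = s$cds_count, stringsAsFactors = FALSE)
  }))
  f_stats <- file.path(out_dir, "genome_stats.tsv")
  utils::write.table(stats_df, f_stats, sep = "\t", quote = FALSE, row.names = FALSE)
  mark("genome_stats", "done", f_stats)

  proteomes <- stats::setNames(lapply(ids, function(g)
    derive_proteome(genomes[[g]], features_list[[g]])), ids)

  hits <- all_vs_all(proteomes)
  rbh <- build_rbh_all(hits, ids)
  ogset <- cluster_ogs(rbh, hits, proteomes)
  mats <- og_matrices(ogset)
  f_og <- file.path(out_dir, c("og_counts.tsv", "og_sharing.tsv", "og_membership.tsv"))
  write_matrix_tsv(mats$counts, f_og[1], "og_id")
  utils::write.table(mats$sharing, f_og[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ogset$membership, f_og[3], sep = "\t", quote = FALSE, row.names = FALSE)
  mark("orthology", "done", f_og)

  bundle <- list(stats = stats_df, ogset = ogset, og_matrices = mats,
                 truth = truth)

  if (isTRUE(st$ani)) {
    ani <- ani_matrix(genomes)
    f <- file.path(out_dir, "ani_matrix.tsv")
    write_matrix_tsv(ani$matrix, f, "genome_id")
    bundle$ani <- ani
    mark("ani", "done", f)
  } else mark("ani", "skipped")

  if (isTRUE(st$aai)) {
    aai <- compute_aai(rbh)
    f <- file.path(out_dir, "aai_matrix.tsv")
    write_matrix_tsv(aai$matrix, f, "genome_id")
    bundle$aai <- aai
    mark("aai", "done", f)
  } else mark("aai", "skipped")

  if (isTRUE(st$phylogenomics) && length(ids) >= 3L) {
    tr <- tryCatch({
      sc <- select_single_copy(ogset)
      sm <- build_supermatrix(sc, ogset, proteomes)
      write_supermatrix(sm, file.path(out_dir, "supermatrix"))
      bootstrap_support(sm, n_reps = bootstrap_reps,
                        seed = derive_seed(seed, 97L))
    }, error = function(e) e)
    if (inherits(tr, "error")) {
      mark("phylogenomics", paste("failed:", conditionMessage(tr)))
    } else {
      f <- file.path(out_dir, "tree.nwk")
      ape::write.tree(tr, f)
      bundle$tree <- tr
      mark("phylogenomics", "done", f)
    }
  } else mark("phylogenomics", "skipped")

  if (isTRUE(st$cytochromes)) {
    heme <- do.call(rbind, lapply(ids, function(g)
      scan_proteome_hemes(proteomes[[g]], pattern_mode = heme_mode)))
    ogc <- ogc_profile(heme, ogset)
    f <- file.path(out_dir, c("heme_scan.tsv", "ogc_matrix.tsv"))
    utils::write.table(heme, f[1], sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(ogc$matrix, f[2], "ogc_id")
    bundle$heme <- heme; bundle$ogc <- ogc
    mark("cytochromes", "done", f)
  } else mark("cytochromes", "skipped")

  if (isTRUE(st$chemotaxis)) {
    chem <- stats::setNames(lapply(ids, function(g)
      map_chemotaxis(features_list[[g]], proteomes[[g]])), ids)
    fla <- stats::setNames(lapply(ids, function(g)
      flagellar_census(features_list[[g]])), ids)
    cl <- do.call(rbind, lapply(ids, function(g) {
      x <- chem[[g]]$clusters
      if (nrow(x)) cbind(genome_id = g, x) else NULL
    }))
    f <- file.path(out_dir, c("che_clusters.tsv", "mcp_classes.tsv",
                              "flagellar_census.json"))
    utils::write.table(cl %||% data.frame(), f[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mcp <- do.call(rbind, lapply(ids, function(g) {
      x <- chem[[g]]$mcp_classes
      if (!is.null(x) && nrow(x)) cbind(genome_id = g, x) else NULL
    }))
    utils::write.table(mcp %||% data.frame(), f[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(fla, f[3], auto_unbox = TRUE, digits = NA)
    bundle$chemotaxis <- chem; bundle$flagellar <- fla
    mark("chemotaxis", "done", f)
  } else mark("chemotaxis", "skipped")

  if (isTRUE(st$mobilome)) {
    lib <- is_library %||% is_reference_library()
    isf <- is_family_matrix(features_list, proteomes, lib)
    f <- file.path(out_dir, c("is_family_matrix.tsv", "transposase_census.tsv"))
    write_matrix_tsv(isf$matrix, f[1], "family")
    cen <- do.call(rbind, lapply(ids, function(g)
      data.frame(genome_id = g, count = isf$census[[g]]$count,
                 cds_count = isf$census[[g]]$cds_count,
                 fraction_of_cds = isf$census[[g]]$fraction_of_cds,
                 stringsAsFactors = FALSE)))
    utils::write.table(cen, f[2], sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$is_families <- isf
    mark("mobilome", "done", f)
  } else mark("mobilome", "skipped")

  if (isTRUE(st$clustering) && length(ids) >= 2L) {
    dendro <- list()
    mats_to_cluster <- list(og = mats$counts)
    if (!is.null(bundle$ogc) && nrow(bundle$ogc$matrix) >= 1L)
      mats_to_cluster$ogc <- bundle$ogc$matrix
    if (!is.null(bundle$is_families) && nrow(bundle$is_families$matrix) >= 1L)
      mats_to_cluster$is_family <- bundle$is_families$matrix
    files <- character(0)
    for (nm in names(mats_to_cluster)) {
      m <- mats_to_cluster[[nm]]
      ok_cols <- colSums(m) > 0
      if (sum(ok_cols) < 2L) next
      hc <- hierarchical_cluster(m[, ok_cols, drop = FALSE], "columns")
      dendro[[nm]] <- hc
      f <- file.path(out_dir, sprintf("dendrogram_%s.nwk", nm))
      ape::write.tree(ape::as.phylo(hc), f)
      files <- c(files, f)
    }
    bundle$dendrograms <- dendro
    mark("clustering", "done", files)
  } else mark("clustering", "skipped")

  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$index <- index
  bundle$out_dir <- out_dir
  class(bundle) <- "ReportBundle"
  invisible(bundle)
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle in", x$out_dir, "\n")
  for (nm in names(x$index$sections))
    cat(sprintf("  %-14s %s\n", nm, x$index$sections[[nm]]$status))
  invisible(x)
}
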