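# All-vs-all protein similarity, reciprocal best hits, orthologous-group
# clustering (RBH graph + in-paralog rule + connected components), OG
# accounting and AAI.

aa_kmers <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' All-vs-all protein similarity search
#'
#' Ordered protein pairs sharing at least one k-mer seed are aligned with
#' a gapped local alignment (BLOSUM62, affine gaps open 11 / extend 1).
#' Hits below the identity or query-coverage thresholds are dropped. The
#' hit list is symmetric in content: a retained A-to-B hit implies the
#' B-to-A hit (same alignment, coverage computed per direction).
#'
#' @param proteomes Named list of proteome data frames (see
#'   [derive_proteome()]); disrupted proteins are excluded.
#' @param min_identity Minimum percent identity (matches / aligned
#'   columns * 100).
#' @param min_coverage Minimum aligned fraction of the query.
#' @param kmer_prefilter_k Seed k-mer length (`0` disables the prefilter
#'   and aligns every pair).
#' @return Data frame of hits: `query_id, subject_id, query_genome,
#'   subject_genome, identity, coverage, score`.
#' @export
all_vs_all <- function(proteomes, min_identity = 30, min_coverage = 0.5,
                       kmer_prefilter_k = 5L) {
  if (length(proteomes) < 1L) stopf("need at least one proteome")
  for (g in names(proteomes))
    if (nrow(clean_proteome(proteomes[[g]])) == 0L)
      stopf("empty proteome for genome '%s'", g)
  prot <- do.call(rbind, lapply(proteomes, clean_proteome))
  rownames(prot) <- NULL
  n <- nrow(prot)
  seqs <- stats::setNames(prot$sequence, prot$protein_id)
  genome_of <- stats::setNames(prot$genome_id, prot$protein_id)

  if (kmer_prefilter_k > 0L) {
    km <- aa_kmers(seqs, kmer_prefilter_k)
    dt <- data.table::data.table(
      kmer = unlist(km, use.names = FALSE),
      idx = rep(seq_len(n), lengths(km)))
    pairs <- merge(dt, dt, by = "kmer", allow.cartesian = TRUE)
    pairs <- unique(pairs[pairs$idx.x < pairs$idx.y, c("idx.x", "idx.y")])
    i1 <- pairs$idx.x; i2 <- pairs$idx.y
  } else {
    cmb <- utils::combn(n, 2L)
    i1 <- cmb[1L, ]; i2 <- cmb[2L, ]
  }
  if (!length(i1))
    return(data.frame(query_id = character(), subject_id = character(),
                      query_genome = character(), subject_genome = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs[i1]), Biostrings::AAStringSet(seqs[i2]),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  ncol_aln <- aln_ncol(aln)
  ident <- 100 * Biostrings::nmatch(aln) / ncol_aln
  sc <- Biostrings::score(aln)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  cov1 <- (Biostrings::end(p) - Biostrings::start(p) + 1L) / nchar(seqs[i1])
  cov2 <- (Biostrings::end(s) - Biostrings::start(s) + 1L) / nchar(seqs[i2])

  fwd <- data.frame(query_id = names(seqs)[i1], subject_id = names(seqs)[i2],
                    identity = ident, coverage = cov1, score = sc,
                    stringsAsFactors = FALSE)
  rev <- data.frame(query_id = names(seqs)[i2], subject_id = names(seqs)[i1],
                    identity = ident, coverage = cov2, score = sc,
                    stringsAsFactors = FALSE)
  hits <- rbind(fwd, rev)
  hits <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
               drop = FALSE]
  hits$query_genome <- unname(genome_of[hits$query_id])
  hits$subject_genome <- unname(genome_of[hits$subject_id])
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "subject_id", "query_genome", "subject_genome",
           "identity", "coverage", "score")]
}

best_hit_per_query <- function(hits) {
  o <- order(hits$query_id, -hits$score, -hits$identity, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal best hits between two genomes
#'
#' Each gene's best hit is its maximum-score hit (ties broken by higher
#' identity, then lexicographic subject id); a pair is kept iff the two
#' genes are mutually best.
#'
#' @param hits Hit table from [all_vs_all()].
#' @param genomeA,genomeB Genome ids.
#' @return Data frame `gene_a, gene_b, genome_a, genome_b, identity,
#'   coverage_a, coverage_b, score` (one row per RBH pair).
#' @export
build_rbh <- function(hits, genomeA, genomeB) {
  ab <- hits[hits$query_genome == genomeA & hits$subject_genome == genomeB, , drop = FALSE]
  ba <- hits[hits$query_genome == genomeB & hits$subject_genome == genomeA, , drop = FALSE]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      genome_a = character(), genome_b = character(),
                      identity = numeric(), coverage_a = numeric(),
                      coverage_b = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(ab) || !nrow(ba)) return(empty)
  best_ab <- best_hit_per_query(ab)
  best_ba <- best_hit_per_query(ba)
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  mutual <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  m <- best_ab[mutual, , drop = FALSE]
  if (!nrow(m)) return(empty)
  covb <- stats::setNames(best_ba$coverage, best_ba$query_id)
  out <- data.frame(gene_a = m$query_id, gene_b = m$subject_id,
                    genome_a = genomeA, genome_b = genomeB,
                    identity = m$identity, coverage_a = m$coverage,
                    coverage_b = unname(covb[m$subject_id]), score = m$score,
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' RBH pairs over every genome pair
#'
#' @param hits Hit table from [all_vs_all()].
#' @param genome_ids Genome ids (default: all in `hits`).
#' @return Row-bound [build_rbh()] tables.
#' @export
build_rbh_all <- function(hits, genome_ids = NULL) {
  ids <- sort(genome_ids %||% unique(c(hits$query_genome, hits$subject_genome)))
  out <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b)
    out[[length(out) + 1L]] <- build_rbh(hits, ids[a], ids[b])
  do.call(rbind, out)
}

#' Cluster genes into orthologous groups
#'
#' Graph nodes are genes; edges are all inter-genome RBH pairs, plus
#' within-genome edges (g, h) whenever `score(g, h)` is at least g's best
#' inter-genome score (in-paralog rule). OGs are connected components of
#' size >= 2; remaining genes are singletons. Output is invariant under
#' genome and gene input order: OG ids are assigned after sorting
#' components by their lexicographically smallest member.
#'
#' @param rbh_pairs Output of [build_rbh_all()].
#' @param hits Full hit table (supplies within-genome scores).
#' @param proteomes Named list of proteome data frames (defines the gene
#'   universe; disrupted proteins excluded).
#' @return An `OrthologousGroupSet`: list with `membership` (data frame
#'   `protein_id, genome_id, og_id` with `NA` og for singletons), `og`
#'   (named list of member vectors), `genomes`, `n_genes`.
#' @export
cluster_ogs <- function(rbh_pairs, hits, proteomes) {
  prot <- do.call(rbind, lapply(proteomes, clean_proteome))
  all_ids <- sort(prot$protein_id)
  genome_of <- stats::setNames(prot$genome_id, prot$protein_id)

  inter <- hits[hits$query_genome != hits$subject_genome, , drop = FALSE]
  best_inter <- tapply(inter$score, inter$query_id, max)
  within <- hits[hits$query_genome == hits$subject_genome, , drop = FALSE]
  if (nrow(within)) {
    thr <- best_inter[within$query_id]
    keep <- is.na(thr) | within$score >= thr
    within <- within[keep, , drop = FALSE]
  }
  edges <- rbind(
    if (nrow(rbh_pairs)) data.frame(a = rbh_pairs$gene_a, b = rbh_pairs$gene_b,
                                    stringsAsFactors = FALSE),
    if (nrow(within)) data.frame(a = within$query_id, b = within$subject_id,
                                 stringsAsFactors = FALSE))
  g <- igraph::make_empty_graph(n = length(all_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_ids)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$a, all_ids), match(edges$b, all_ids)))
  comp <- igraph::components(g)
  members <- split(all_ids, comp$membership)
  members <- members[order(vapply(members, min, character(1)))]
  og_sizes <- lengths(members)
  ogs <- members[og_sizes >= 2L]
  names(ogs) <- sprintf("OG%05d", seq_along(ogs))
  og_of <- stats::setNames(rep(names(ogs), lengths(ogs)), unlist(ogs))
  membership <- data.frame(protein_id = all_ids,
                           genome_id = unname(genome_of[all_ids]),
                           og_id = unname(og_of[all_ids]),
                           stringsAsFactors = FALSE)
  structure(list(membership = membership, og = ogs,
                 genomes = sort(unique(prot$genome_id)),
                 n_genes = length(all_ids)),
            class = "OrthologousGroupSet")
}

#' @export
print.OrthologousGroupSet <- function(x, ...) {
  cat(sprintf("OrthologousGroupSet: %d OGs over %d genomes, %d/%d genes assigned\n",
              length(x$og), length(x$genomes),
              sum(!is.na(x$membership$og_id)), x$n_genes))
  invisible(x)
}

#' OG count/presence matrices and the sharing table
#'
#' @param ogset An `OrthologousGroupSet`.
#' @return List with `counts` (OG x genome member counts), `presence`
#'   (0/1), `sharing` (for every nonempty genome subset with at least one
#'   OG: the number of OGs present in exactly that subset), `core_count`,
#'   `single_copy_count`, and `fraction_assigned` (percent of genes in
#'   OGs, one decimal).
#' @export
og_matrices <- function(ogset) {
  genomes <- ogset$genomes
  m <- ogset$membership[!is.na(ogset$membership$og_id), , drop = FALSE]
  counts <- table(factor(m$og_id, levels = names(ogset$og)),
                  factor(m$genome_id, levels = genomes))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  presence <- (counts > 0) + 0L
  sig <- apply(presence, 1L, function(r) paste(genomes[r == 1L], collapse = "+"))
  sharing <- as.data.frame(table(sig), stringsAsFactors = FALSE)
  names(sharing) <- c("genome_subset", "n_ogs")
  sharing <- sharing[order(-sharing$n_ogs, sharing$genome_subset), , drop = FALSE]
  rownames(sharing) <- NULL
  full <- paste(genomes, collapse = "+")
  core <- sum(rowSums(presence) == length(genomes))
  single <- sum(apply(counts, 1L, function(r) all(r == 1L)))
  list(counts = counts, presence = presence, sharing = sharing,
       core_count = core, single_copy_count = single,
       fraction_assigned = round1(100 * nrow(m) / ogset$n_genes))
}

#' Average amino-acid identity per genome pair
#'
#' AAI is the unweighted mean percent identity over RBH pairs passing the
#' identity and coverage filters (two-way convention: both directions'
#' query coverage must pass).
#'
#' @param rbh_pairs Output of [build_rbh_all()].
#' @param min_identity Minimum percent identity per pair (default 30).
#' @param min_coverage Minimum aligned fraction of each gene (default 0.7).
#' @return List with `table` (`genome_a, genome_b, aai, n_pairs`) and
#'   `matrix` (symmetric, `NA` where no qualifying pair; diagonal 100).
#' @export
compute_aai <- function(rbh_pairs, min_identity = 30, min_coverage = 0.7) {
  ids <- sort(unique(c(rbh_pairs$genome_a, rbh_pairs$genome_b)))
  rows <- list()
  mat <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(mat) <- 100
  for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b) {
    p <- rbh_pairs[rbh_pairs$genome_a == ids[a] & rbh_pairs$genome_b == ids[b], ,
                   drop = FALSE]
    p <- p[p$identity >= min_identity & p$coverage_a >= min_coverage &
             p$coverage_b >= min_coverage, , drop = FALSE]
    aai <- if (nrow(p)) round1(mean(p$identity)) else NA_real_
    if (!nrow(p))
      warnf("no qualifying RBH pairs for %s vs %s; AAI undefined", ids[a], ids[b])
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = ids[a], genome_b = ids[b], aai = aai, n_pairs = nrow(p),
      stringsAsFactors = FALSE)
    mat[a, b] <- mat[b, a] <- aai
  }
  list(table = do.call(rbind, rows), matrix = mat)
}
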