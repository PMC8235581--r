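# Single-copy marker selection, per-gene progressive alignment,
# concatenated supermatrix, Poisson-corrected distances, neighbor-joining
# tree and bootstrap support.

#' Select single-copy orthologous groups
#'
#' @param ogset An `OrthologousGroupSet` over at least 3 genomes.
#' @param required_fraction Minimum fraction of genomes in which the OG
#'   must have exactly one member (default 1.0); no genome may have more
#'   than one member.
#' @return Sorted character vector of OG ids.
#' @export
select_single_copy <- function(ogset, required_fraction = 1.0) {
  if (length(ogset$genomes) < 3L) stopf("need an ogset over >= 3 genomes")
  mats <- og_matrices(ogset)
  cnt <- mats$counts
  ok <- apply(cnt, 1L, function(r)
    all(r <= 1L) && sum(r == 1L) >= required_fraction * ncol(cnt))
  ids <- sort(rownames(cnt)[ok])
  if (!length(ids))
    stopf("no single-copy OGs at required_fraction=%.2f; lower it", required_fraction)
  ids
}

# ---- progressive multiple alignment -------------------------------------

kmer_distance <- function(seqs, k = 3L) {
  km <- aa_kmers(seqs, k)
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    u <- length(union(km[[i]], km[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0L) 0 else
      1 - length(intersect(km[[i]], km[[j]])) / u
  }
  d
}

consensus_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("A")
    tb <- table(col)
    names(tb)[which.max(tb)]  # ties: first alphabetically (table is sorted)
  })
}

# Align sequences progressively: guide order by k-mer distance (most
# central first), each new sequence globally aligned to the running
# consensus; consensus-side gaps open new all-gap columns in the profile.
progressive_align <- function(seqs) {
  n <- length(seqs)
  if (n == 1L) return(seqs)
  d <- kmer_distance(seqs)
  ord <- order(rowSums(d), names(seqs))
  aln <- stats::setNames(seqs[ord[1]], names(seqs)[ord[1]])
  for (i in ord[-1]) {
    cons <- paste(consensus_of(aln), collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(cons),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    newrow <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    consrow <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    # map alignment columns back onto profile columns; consensus gaps
    # are insertions relative to the existing profile
    old <- do.call(rbind, strsplit(unname(aln), ""))
    out_old <- matrix("-", nrow(old), length(consrow))
    ci <- 0L
    for (col in seq_along(consrow)) {
      if (consrow[col] != "-") {
        ci <- ci + 1L
        out_old[, col] <- old[, ci]
      }
    }
    aln <- stats::setNames(c(apply(out_old, 1L, paste, collapse = ""),
                             paste(newrow, collapse = "")),
                           c(names(aln), names(seqs)[i]))
  }
  aln[names(seqs)]
}

#' Build the concatenated single-copy supermatrix
#'
#' Each selected OG is aligned by progressive alignment (guide order from
#' k-mer distances, global pairwise alignment against the running profile
#' consensus) and the per-gene alignments are concatenated. Supply
#' `aligner` to substitute an external aligner: a function
#' `(named character) -> named character` of equal-length aligned rows.
#'
#' @param single_copy_ogs OG ids from [select_single_copy()].
#' @param ogset The `OrthologousGroupSet`.
#' @param proteomes Named list of proteome data frames.
#' @param aligner Optional replacement alignment function.
#' @return A `Supermatrix`: list with `taxa`, `alignment` (named
#'   equal-length character rows over amino acids and `-`), `partition`
#'   (data frame `og_id, start, end`, 0-based half-open columns).
#' @export
build_supermatrix <- function(single_copy_ogs, ogset, proteomes,
                              aligner = NULL) {
  aligner <- aligner %||% progressive_align
  prot <- do.call(rbind, lapply(proteomes, clean_proteome))
  seq_of <- stats::setNames(prot$sequence, prot$protein_id)
  taxa <- ogset$genomes
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list(); col0 <- 0L
  for (og in single_copy_ogs) {
    members <- ogset$og[[og]]
    gmap <- ogset$membership$genome_id[match(members, ogset$membership$protein_id)]
    if (!setequal(gmap, taxa) || anyDuplicated(gmap))
      stopf("OG %s is not single-copy across all taxa", og)
    seqs <- stats::setNames(unname(seq_of[members]), gmap)[taxa]
    a <- aligner(seqs)
    w <- unique(nchar(a))
    if (length(w) != 1L) stopf("aligner returned ragged rows for %s", og)
    rows <- stats::setNames(paste0(rows, a[taxa]), taxa)
    parts[[og]] <- data.frame(og_id = og, start = col0, end = col0 + w,
                              stringsAsFactors = FALSE)
    col0 <- col0 + w
  }
  structure(list(taxa = taxa, alignment = rows,
                 partition = do.call(rbind, c(parts, list(make.row.names = FALSE)))),
            class = "Supermatrix")
}

#' @export
print.Supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d columns (%d partitions)\n",
              length(x$taxa), nchar(x$alignment[1]), nrow(x$partition)))
  invisible(x)
}

supermatrix_chars <- function(sm) {
  do.call(rbind, strsplit(unname(sm$alignment[sm$taxa]), ""))
}

#' Pairwise distances from a supermatrix
#'
#' p-distance = mismatches / compared columns under pairwise deletion
#' (columns where either row has a gap are dropped for that pair);
#' Poisson correction d = -ln(1 - p).
#'
#' @param supermatrix A `Supermatrix` (or a plain character matrix of
#'   single characters, rows = taxa).
#' @param model `"poisson"` (default) or `"p-distance"`.
#' @return Symmetric distance matrix with a `model` attribute.
#' @export
distance_matrix <- function(supermatrix, model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  m <- if (inherits(supermatrix, "Supermatrix")) supermatrix_chars(supermatrix)
       else supermatrix
  taxa <- if (inherits(supermatrix, "Supermatrix")) supermatrix$taxa
          else rownames(supermatrix)
  n <- nrow(m)
  if (n < 2L) stopf("need >= 2 taxa")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stopf("zero comparable columns for pair %s / %s", taxa[i], taxa[j])
    p <- mean(m[i, ok] != m[j, ok])
    if (model == "poisson") {
      if (p >= 1) stopf("p-distance >= 1 for pair %s / %s; Poisson correction undefined",
                        taxa[i], taxa[j])
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric distance
#' matrix; taxa are pre-sorted by label so ties resolve deterministically.
#' Negative estimated branch lengths are clamped to zero with the deficit
#' moved to the sibling branch.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @return An [ape::phylo] tree (unrooted for >= 4 taxa).
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stopf("distance matrix is not symmetric")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib)) {
      sib <- sib[1L]
      tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Columns of the supermatrix are resampled with replacement `n_reps`
#' times; the support of each internal bipartition of the full-data tree
#' is the fraction of replicate trees containing it. Supports are stored
#' as node labels (fractions in `[0, 1]`).
#'
#' @param supermatrix A `Supermatrix`.
#' @param n_reps Bootstrap replicates (default 100).
#' @param seed Seed making the resampling deterministic.
#' @param model Distance model, see [distance_matrix()].
#' @return The full-data [ape::phylo] tree with `node.label` supports and
#'   a `bootstrap` attribute (`n_reps`).
#' @export
bootstrap_support <- function(supermatrix, n_reps = 100L, seed = 1L,
                              model = "poisson") {
  if (n_reps < 1L) stopf("n_reps must be >= 1")
  chars <- supermatrix_chars(supermatrix)
  rownames(chars) <- supermatrix$taxa
  full <- nj_tree(distance_matrix(chars, model))
  reps <- with_rng(seed, lapply(seq_len(n_reps), function(r) {
    cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
    nj_tree(distance_matrix(chars[, cols, drop = FALSE], model))
  }))
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  full$node.label <- formatC(cnt / n_reps, format = "g")
  attr(full, "bootstrap") <- n_reps
  full
}

#' Write a supermatrix as FASTA and relaxed PHYLIP with a partition map
#'
#' @param supermatrix A `Supermatrix`.
#' @param prefix Output path prefix; writes `<prefix>.faa`,
#'   `<prefix>.phy`, `<prefix>.partitions.tsv`.
#' @export
write_supermatrix <- function(supermatrix, prefix) {
  aa <- Biostrings::AAStringSet(supermatrix$alignment)
  Biostrings::writeXStringSet(aa, paste0(prefix, ".faa"), width = 80L)
  phy <- c(sprintf("%d %d", length(supermatrix$taxa),
                   nchar(supermatrix$alignment[1])),
           sprintf("%s  %s", supermatrix$taxa,
                   unname(supermatrix$alignment[supermatrix$taxa])))
  writeLines(phy, paste0(prefix, ".phy"))
  utils::write.table(supermatrix$partition, paste0(prefix, ".partitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
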