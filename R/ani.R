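# Fragment-recruitment average nucleotide identity (ANIb-style): the query
# genome is cut into consecutive 1020-bp fragments, each is placed on the
# subject by shared-k-mer seeding and aligned with a gapped extension;
# fragments passing the 30% identity / 70% alignment-fraction filters
# contribute to the direction mean, and the reported ANI is the mean of
# the two direction means.

# k-mer position index of one genome (both replicons concatenated is
# avoided: positions are per replicon)
index_kmers <- function(genome, k) {
  tabs <- lapply(names(genome$replicons), function(rid) {
    s <- as.character(genome$replicons[[rid]])
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
                           replicon = rid, pos = 1:(n - k + 1L))
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  idx
}

fragment_seq <- function(genome, fragment_len) {
  out <- list()
  for (rid in names(genome$replicons)) {
    s <- as.character(genome$replicons[[rid]])
    n_full <- nchar(s) %/% fragment_len
    if (n_full == 0L) next
    st <- (seq_len(n_full) - 1L) * fragment_len + 1L
    out[[rid]] <- substring(s, st, st + fragment_len - 1L)
  }
  unlist(out, use.names = FALSE)
}

# Best candidate window (replicon, start, end, strand) for one fragment,
# by modal seed diagonal; NULL when no seed matches.
seed_window <- function(frag, idx, k, stride, pad, subject_lens) {
  score_hits <- function(fr) {
    n <- nchar(fr)
    starts <- seq(1L, n - k + 1L, by = stride)
    kms <- substring(fr, starts, starts + k - 1L)
    idx[data.table::data.table(kmer = kms, qpos = starts),
        on = "kmer", nomatch = NULL]
  }
  pick <- function(h) {
    if (!nrow(h)) return(NULL)
    h$diag <- h$pos - h$qpos
    h$bin <- paste(h$replicon, h$diag %/% 50L)
    tb <- sort(table(h$bin), decreasing = TRUE)
    best <- names(tb)[1]
    hb <- h[h$bin == best, ]
    list(replicon = hb$replicon[1], diag = stats::median(hb$diag),
         n = nrow(h), n_best = nrow(hb))
  }
  fwd <- pick(score_hits(frag))
  rcf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  rev <- pick(score_hits(rcf))
  use_rev <- !is.null(rev) && (is.null(fwd) || rev$n_best > fwd$n_best)
  best <- if (use_rev) rev else fwd
  if (is.null(best)) return(NULL)
  L <- subject_lens[[best$replicon]]
  start <- max(1L, as.integer(best$diag) + 1L - pad)
  end <- min(L, as.integer(best$diag) + nchar(frag) + pad)
  list(replicon = best$replicon, start = start, end = end,
       strand = if (use_rev) "-" else "+",
       frag = if (use_rev) rcf else frag)
}

ani_direction <- function(qry, sbj, fragment_len, min_identity, min_aln_cov,
                          seed_k, stride = 5L, pad = 60L) {
  frags <- fragment_seq(qry, fragment_len)
  total <- length(frags)
  if (!total) return(list(mean = NA_real_, used = 0L, total = 0L))
  idx <- index_kmers(sbj, seed_k)
  lens <- stats::setNames(as.integer(Biostrings::width(sbj$replicons)),
                          names(sbj$replicons))
  wins <- lapply(frags, seed_window, idx = idx, k = seed_k, stride = stride,
                 pad = pad, subject_lens = lens)
  ok <- !vapply(wins, is.null, logical(1))
  if (!any(ok)) return(list(mean = NA_real_, used = 0L, total = total))
  pat <- Biostrings::DNAStringSet(vapply(wins[ok], `[[`, "", "frag"))
  sub <- Biostrings::DNAStringSet(vapply(wins[ok], function(w)
    as.character(Biostrings::subseq(sbj$replicons[[w$replicon]], w$start, w$end)),
    character(1)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(pat, sub, type = "global-local",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  ncols <- aln_ncol(aln)
  ident <- 100 * Biostrings::nmatch(aln) / ncols
  p <- Biostrings::pattern(aln)
  aligned_frac <- (Biostrings::end(p) - Biostrings::start(p) + 1L) /
    Biostrings::width(pat)
  keep <- ident >= min_identity & aligned_frac >= min_aln_cov
  list(mean = if (any(keep)) mean(ident[keep]) else NA_real_,
       used = sum(keep), total = total)
}

#' Fragment-recruitment average nucleotide identity between two genomes
#'
#' @param genomeA,genomeB `GenomeRecord`s.
#' @param fragment_len Fragment length (default 1020 bp, the ANIb
#'   convention; the terminal short fragment of each replicon is
#'   discarded).
#' @param min_identity Fragment retention: minimum percent identity.
#' @param min_aln_cov Fragment retention: minimum aligned fraction of the
#'   fragment.
#' @param seed_k Seed k-mer length for fragment placement.
#' @return An `AniResult` list: `ani_percent` (mean of the two direction
#'   means, one decimal; `NA` when no fragment is retained in either
#'   direction), `mean_ab`, `mean_ba`, `fragments_used_ab/ba`,
#'   `fragments_total_ab/ba`.
#' @export
fragment_ani <- function(genomeA, genomeB, fragment_len = 1020L,
                         min_identity = 30, min_aln_cov = 0.7, seed_k = 15L) {
  if (fragment_len < 100L) stopf("fragment_len must be >= 100")
  ab <- ani_direction(genomeA, genomeB, fragment_len, min_identity,
                      min_aln_cov, seed_k)
  ba <- ani_direction(genomeB, genomeA, fragment_len, min_identity,
                      min_aln_cov, seed_k)
  means <- c(ab$mean, ba$mean)
  ani <- if (all(is.na(means))) {
    warnf("no fragment retained between %s and %s; ANI undefined",
          genomeA$genome_id, genomeB$genome_id)
    NA_real_
  } else round1(mean(means, na.rm = TRUE))
  structure(list(genome_a = genomeA$genome_id, genome_b = genomeB$genome_id,
                 ani_percent = ani, mean_ab = ab$mean, mean_ba = ba$mean,
                 fragments_used_ab = ab$used, fragments_total_ab = ab$total,
                 fragments_used_ba = ba$used, fragments_total_ba = ba$total),
            class = "AniResult")
}

#' @export
print.AniResult <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %.1f%% (A>B %.2f on %d/%d; B>A %.2f on %d/%d)\n",
              x$genome_a, x$genome_b, x$ani_percent,
              x$mean_ab, x$fragments_used_ab, x$fragments_total_ab,
              x$mean_ba, x$fragments_used_ba, x$fragments_total_ba))
  invisible(x)
}

#' All-pairs ANI matrix
#'
#' @param genomes Named list of `GenomeRecord`s.
#' @param ... Passed to [fragment_ani()].
#' @return List with `matrix` (symmetric, diagonal 100) and `table` (one
#'   row per pair).
#' @export
ani_matrix <- function(genomes, ...) {
  ids <- names(genomes)
  mat <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(mat) <- 100
  rows <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b) {
    r <- fragment_ani(genomes[[a]], genomes[[b]], ...)
    mat[a, b] <- mat[b, a] <- r$ani_percent
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = ids[a], genome_b = ids[b], ani = r$ani_percent,
      mean_ab = r$mean_ab, mean_ba = r$mean_ba, stringsAsFactors = FALSE)
  }
  list(matrix = mat, table = do.call(rbind, rows))
}
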