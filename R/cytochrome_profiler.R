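# Multiheme c-type cytochrome detection by heme-binding motif counting,
# and the OGC-by-genome profile matrix.

HEME_PATTERNS <- list(
  # canonical c-heme binding motifs CXXCH / CXXXCH
  canonical = "C..CH|C...CH",
  # the looser literal reading CXXH / CXXXH
  literal = "C..H|C...H")

#' Scan a protein for heme-binding motifs
#'
#' Scanning is left-to-right, greedily taking the shortest match at each
#' position and resuming after the matched H, so tandem motifs are
#' counted without overlap. Case-insensitive.
#'
#' @param protein Protein sequence (character scalar) or a one-row
#'   proteome data frame.
#' @param pattern_mode `"canonical"` (CXXCH / CXXXCH, default) or
#'   `"literal"` (CXXH / CXXXH).
#' @param threshold Multiheme flag threshold, see [classify_multiheme()].
#' @return A `HemeScanResult` list: `protein_id`, `motif_positions`
#'   (0-based starts, strictly increasing), `motif_count`, `is_multiheme`,
#'   `pattern_mode`.
#' @export
scan_heme_motifs <- function(protein, pattern_mode = c("canonical", "literal"),
                             threshold = 4L) {
  pattern_mode <- match.arg(pattern_mode)
  if (is.data.frame(protein)) {
    pid <- protein$protein_id[1]
    seq <- protein$sequence[1]
  } else {
    pid <- NA_character_
    seq <- protein
  }
  if (!nzchar(seq)) stopf("empty protein")
  up <- toupper(seq)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", up))
    stopf("protein contains non-amino-acid characters")
  m <- gregexpr(HEME_PATTERNS[[pattern_mode]], up, perl = TRUE)[[1]]
  pos <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  structure(list(protein_id = pid, motif_positions = pos,
                 motif_count = length(pos),
                 is_multiheme = length(pos) >= threshold,
                 pattern_mode = pattern_mode),
            class = "HemeScanResult")
}

#' Multiheme flag from a heme scan
#'
#' The multiheme criterion "more than 3 motifs" is read strictly as
#' `motif_count >= 4`; the threshold is configurable (much of the
#' literature uses 3).
#'
#' @param scan A `HemeScanResult`.
#' @param threshold Minimum motif count (default 4).
#' @return Logical flag.
#' @export
classify_multiheme <- function(scan, threshold = 4L) {
  scan$motif_count >= threshold
}

#' Scan a whole proteome for heme motifs
#'
#' @param proteome Proteome data frame.
#' @param pattern_mode,threshold See [scan_heme_motifs()].
#' @return Data frame `protein_id, genome_id, motif_count, is_multiheme,
#'   pattern_mode`.
#' @export
scan_proteome_hemes <- function(proteome, pattern_mode = "canonical",
                                threshold = 4L) {
  pr <- clean_proteome(proteome)
  counts <- vapply(pr$sequence, function(s)
    scan_heme_motifs(s, pattern_mode, threshold)$motif_count, integer(1),
    USE.NAMES = FALSE)
  data.frame(protein_id = pr$protein_id, genome_id = pr$genome_id,
             motif_count = counts, is_multiheme = counts >= threshold,
             pattern_mode = pattern_mode, stringsAsFactors = FALSE)
}

#' OGC-by-genome count matrix
#'
#' OGCs are the orthologous groups containing at least one multiheme
#' protein; entries are per-genome counts of multiheme members. Singleton
#' multiheme proteins (not assigned to any OG) are appended as
#' single-member OGC rows.
#'
#' @param heme_table Output of [scan_proteome_hemes()] over all genomes
#'   in the ogset.
#' @param ogset An `OrthologousGroupSet`.
#' @return List with `matrix` (OGC x genome counts) and `ogc_ogs`
#'   (mapping of OGC row to OG id or singleton protein id).
#' @export
ogc_profile <- function(heme_table, ogset) {
  genomes <- ogset$genomes
  mh <- heme_table[heme_table$is_multiheme, , drop = FALSE]
  og_of <- stats::setNames(ogset$membership$og_id, ogset$membership$protein_id)
  mh$og_id <- unname(og_of[mh$protein_id])
  grouped <- mh[!is.na(mh$og_id), , drop = FALSE]
  ogc_ids <- sort(unique(grouped$og_id))
  mat <- matrix(0L, length(ogc_ids), length(genomes),
                dimnames = list(ogc_ids, genomes))
  if (nrow(grouped)) {
    tb <- table(factor(grouped$og_id, ogc_ids), factor(grouped$genome_id, genomes))
    mat[] <- as.integer(tb)
  }
  singles <- mh[is.na(mh$og_id), , drop = FALSE]
  if (nrow(singles)) {
    smat <- matrix(0L, nrow(singles), length(genomes),
                   dimnames = list(paste0("OGC_singleton:", singles$protein_id),
                                   genomes))
    smat[cbind(seq_len(nrow(singles)), match(singles$genome_id, genomes))] <- 1L
    mat <- rbind(mat, smat)
  }
  list(matrix = mat,
       ogc_ogs = c(stats::setNames(ogc_ids, ogc_ids),
                   if (nrow(singles)) stats::setNames(
                     singles$protein_id,
                     paste0("OGC_singleton:", singles$protein_id))))
}
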