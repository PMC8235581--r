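# Transposase census and insertion-sequence family assignment against a
# labeled reference library.

#' Transposase census of one genome
#'
#' A CDS is a transposase when its product string contains "transposase"
#' (case-insensitive). The fraction is 100 * count / cds_count to one
#' decimal. Draft assemblies get a warning: fragmented assemblies
#' underestimate transposable-element counts.
#'
#' @param features Feature data frame.
#' @param assembly_level `"complete"` or `"draft"` (for the warning).
#' @return List `count, cds_count, fraction_of_cds, locus_tags`.
#' @export
transposase_census <- function(features, assembly_level = "complete") {
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) stopf("no CDS features; transposase fraction undefined")
  hit <- grepl("transposase", cds$product, ignore.case = TRUE)
  if (identical(assembly_level, "draft"))
    warnf("draft assembly: transposase counts are likely underestimated")
  list(count = sum(hit), cds_count = nrow(cds),
       fraction_of_cds = round1(100 * sum(hit) / nrow(cds)),
       locus_tags = cds$locus_tag[hit])
}

parse_is_library <- function(library) {
  if (is.character(library) && length(library) == 1L && file.exists(library))
    library <- Biostrings::readAAStringSet(library)
  if (!methods::is(library, "AAStringSet"))
    stopf("library must be an AAStringSet or a FASTA path")
  if (!length(library)) stopf("empty IS reference library")
  fam <- sub(".*family=([^ ]+).*", "\\1", names(library))
  no_tag <- !grepl("family=", names(library))
  fam[no_tag] <- sub("\\s.*$", "", names(library)[no_tag])
  list(seqs = as.character(library), family = fam)
}

#' Assign an IS family to a transposase protein
#'
#' Best local-alignment hit (BLOSUM62) against a labeled reference
#' library; the family is assigned when the best hit passes the identity
#' and query-coverage thresholds. Ties are broken by identity, then by
#' family label order.
#'
#' @param query Protein sequence (character scalar).
#' @param library Named `AAStringSet` (headers carrying `family=` tags)
#'   or path to such a FASTA.
#' @param min_identity Minimum percent identity (default 25).
#' @param min_coverage Minimum aligned fraction of the query (default 0.6).
#' @return List `family` (`NA` when unassigned), `identity`, `coverage`,
#'   `score`.
#' @export
assign_is_family <- function(query, library, min_identity = 25,
                             min_coverage = 0.6) {
  lib <- parse_is_library(library)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(lib$seqs))),
    Biostrings::AAStringSet(lib$seqs),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  ident <- 100 * Biostrings::nmatch(aln) / aln_ncol(aln)
  p <- Biostrings::pattern(aln)
  cov <- (Biostrings::end(p) - Biostrings::start(p) + 1L) / nchar(query)
  sc <- Biostrings::score(aln)
  ok <- ident >= min_identity & cov >= min_coverage
  if (!any(ok))
    return(list(family = NA_character_, identity = NA_real_,
                coverage = NA_real_, score = NA_real_))
  o <- order(-sc, -ident, lib$family, seq_along(sc))
  o <- o[ok[o]][1]
  list(family = lib$family[o], identity = ident[o], coverage = cov[o],
       score = sc[o])
}

#' IS family-by-genome count matrix
#'
#' Runs [transposase_census()] per genome and [assign_is_family()] per
#' transposase protein.
#'
#' @param features_list Named list of feature data frames.
#' @param proteomes Named list of proteome data frames.
#' @param library IS reference library (see [assign_is_family()]).
#' @param ... Thresholds passed to [assign_is_family()].
#' @return List with `matrix` (family x genome counts, `unassigned` row
#'   last), `assignments` (per-transposase table) and `census` (per
#'   genome).
#' @export
is_family_matrix <- function(features_list, proteomes, library, ...) {
  genomes <- names(features_list)
  rows <- list(); census <- list()
  for (g in genomes) {
    cen <- transposase_census(features_list[[g]])
    census[[g]] <- cen
    pr <- clean_proteome(proteomes[[g]])
    for (lt in cen$locus_tags) {
      s <- pr$sequence[match(lt, pr$locus_tag)]
      fam <- if (is.na(s)) NA_character_ else
        assign_is_family(s, library, ...)$family
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, locus_tag = lt,
        family = if (is.na(fam)) "unassigned" else fam,
        stringsAsFactors = FALSE)
    }
  }
  asg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), locus_tag = character(),
               family = character(), stringsAsFactors = FALSE)
  fams <- sort(setdiff(unique(asg$family), "unassigned"))
  lv <- c(fams, "unassigned")
  mat <- matrix(0L, length(lv), length(genomes), dimnames = list(lv, genomes))
  if (nrow(asg)) {
    tb <- table(factor(asg$family, lv), factor(asg$genome_id, genomes))
    mat[] <- as.integer(tb)
  }
  list(matrix = mat, assignments = asg, census = census)
}
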