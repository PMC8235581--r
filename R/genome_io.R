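# Reading and writing annotated genomes, proteome derivation, genome stats.
#
# Internal coordinates are 0-based half-open; GFF3 on disk is the usual
# 1-based inclusive dialect. A feature table may be supplied instead of GFF3
# as a 7-column TSV: replicon, start, end, strand, kind, product, locus_tag
# (1-based inclusive coordinates, like GFF3).

#' Construct a genome record
#'
#' A `GenomeRecord` bundles the replicon sequences of one strain with its
#' identifiers. Sequences are held as a named [Biostrings::DNAStringSet].
#'
#' @param genome_id Unique genome label.
#' @param replicons Named `DNAStringSet` (or named character vector) of
#'   replicon sequences; names are replicon ids, unique within the genome.
#' @param strain_name Free-text strain name.
#' @param assembly_level `"complete"` or `"draft"`.
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(genome_id, replicons, strain_name = genome_id,
                          assembly_level = c("complete", "draft")) {
  assembly_level <- match.arg(assembly_level)
  if (!methods::is(replicons, "DNAStringSet"))
    replicons <- Biostrings::DNAStringSet(unlist(replicons))
  ids <- names(replicons)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stopf("replicon ids must be present and unique within genome '%s'", genome_id)
  if (any(Biostrings::width(replicons) == 0))
    stopf("genome '%s' has an empty replicon", genome_id)
  bad <- Biostrings::letterFrequency(replicons, "ACGTN", as.prob = FALSE)
  if (any(rowSums(bad) != Biostrings::width(replicons)))
    stopf("genome '%s' has characters outside {A,C,G,T,N}", genome_id)
  structure(list(genome_id = genome_id, strain_name = strain_name,
                 replicons = replicons, assembly_level = assembly_level),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s' (%s): %d replicon(s), %s bp\n",
              x$genome_id, x$assembly_level, length(x$replicons),
              format(sum(Biostrings::width(x$replicons)), big.mark = ",")))
  invisible(x)
}

empty_features <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             kind = character(), product = character(),
             locus_tag = character(), partial = logical(),
             stringsAsFactors = FALSE)
}

validate_features <- function(genome, features) {
  rl <- stats::setNames(Biostrings::width(genome$replicons),
                        names(genome$replicons))
  unk <- setdiff(features$replicon_id, names(rl))
  if (length(unk))
    stopf("features reference unknown replicon(s): %s", paste(unk, collapse = ", "))
  bad <- features$start < 0 | features$start >= features$end |
    features$end > rl[features$replicon_id]
  if (any(bad))
    stopf("feature '%s' has coordinates outside its replicon",
          features$feature_id[which(bad)[1]])
  dup <- features$locus_tag[nzchar(features$locus_tag)]
  if (anyDuplicated(dup))
    stopf("duplicate locus_tag: %s", dup[duplicated(dup)][1])
  invisible(TRUE)
}

sort_features <- function(features) {
  features[order(features$replicon_id, features$start, features$end,
                 features$feature_id), , drop = FALSE]
}

#' Read an annotated genome from FASTA plus GFF3 or feature table
#'
#' Coordinates are converted from the 1-based inclusive convention of GFF3
#' (and of the TSV feature table) to 0-based half-open. Features are sorted
#' by (replicon, start); feature kinds other than `CDS` and `pseudogene`
#' are mapped to `"other"`.
#'
#' @param fasta_path Multi-replicon nucleotide FASTA.
#' @param annotation_path GFF3 (`.gff`/`.gff3`) or 7-column TSV feature
#'   table (`replicon, start, end, strand, kind, product, locus_tag`).
#' @param genome_id Genome label; defaults to the FASTA basename.
#' @param strain_name,assembly_level Passed to [genome_record()].
#' @return `list(genome = GenomeRecord, features = data.frame)`.
#' @export
read_annotated_genome <- function(fasta_path, annotation_path,
                                  genome_id = NULL, strain_name = NULL,
                                  assembly_level = "complete") {
  if (!file.exists(fasta_path)) stopf("FASTA not found: %s", fasta_path)
  if (!file.exists(annotation_path)) stopf("annotation not found: %s", annotation_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gid <- genome_id %||% sub("\\.(fa|fna|fasta)$", "", basename(fasta_path))
  genome <- genome_record(gid, seqs, strain_name %||% gid, assembly_level)

  if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    g <- as.data.frame(rtracklayer::readGFF(annotation_path))
    feats <- data.frame(
      feature_id = if ("ID" %in% names(g)) as.character(g$ID) else NA_character_,
      replicon_id = as.character(g$seqid),
      start = as.integer(g$start) - 1L,
      end = as.integer(g$end),
      strand = as.character(g$strand),
      kind = as.character(g$type),
      product = if ("product" %in% names(g)) as.character(g$product) else NA_character_,
      locus_tag = if ("locus_tag" %in% names(g)) as.character(g$locus_tag) else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    tb <- utils::read.table(annotation_path, sep = "\t", header = FALSE,
                            quote = "", comment.char = "#",
                            col.names = c("replicon", "start", "end", "strand",
                                          "kind", "product", "locus_tag"),
                            stringsAsFactors = FALSE)
    feats <- data.frame(
      feature_id = NA_character_, replicon_id = as.character(tb$replicon),
      start = as.integer(tb$start) - 1L, end = as.integer(tb$end),
      strand = as.character(tb$strand), kind = as.character(tb$kind),
      product = as.character(tb$product), locus_tag = as.character(tb$locus_tag),
      stringsAsFactors = FALSE)
  }
  feats$kind[!feats$kind %in% c("CDS", "pseudogene")] <- "other"
  feats$product[is.na(feats$product)] <- ""
  feats$locus_tag[is.na(feats$locus_tag)] <- ""
  noid <- is.na(feats$feature_id) | !nzchar(feats$feature_id)
  feats$feature_id[noid] <- ifelse(nzchar(feats$locus_tag[noid]),
                                   feats$locus_tag[noid],
                                   sprintf("feat%05d", which(noid)))
  feats$partial <- FALSE
  feats <- sort_features(feats)
  rownames(feats) <- NULL
  validate_features(genome, feats)
  list(genome = genome, features = feats)
}

#' Write a genome and its features to FASTA + GFF3
#'
#' The inverse of [read_annotated_genome()]: coordinates go back out as
#' 1-based inclusive GFF3.
#'
#' @param genome A `GenomeRecord`.
#' @param features Feature data frame (0-based half-open).
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotated_genome <- function(genome, features, fasta_path, gff_path) {
  Biostrings::writeXStringSet(genome$replicons, fasta_path, width = 80L)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$replicons),
                     Biostrings::width(genome$replicons)))
  if (nrow(features)) {
    attrs <- sprintf("ID=%s;locus_tag=%s;product=%s", features$feature_id,
                     features$locus_tag, features$product)
    lines <- c(lines, sprintf("%s\tgenosig\t%s\t%d\t%d\t.\t%s\t0\t%s",
                              features$replicon_id, features$kind,
                              features$start + 1L, features$end,
                              features$strand, attrs))
  }
  writeLines(lines, gff_path)
  invisible(c(fasta = fasta_path, gff = gff_path))
}

#' Derive the proteome of an annotated genome
#'
#' CDS features are extracted, reverse-complemented when on the minus
#' strand, and translated with the bacterial genetic code (table 11). The
#' trailing stop is removed. A CDS with an internal stop is returned with
#' `disrupted = TRUE` and is excluded from downstream protein analyses by
#' the callers of this function; a CDS whose length is not divisible by 3
#' is flagged `partial` and translated on its longest in-frame prefix
#' (with a warning).
#'
#' @param genome A `GenomeRecord`.
#' @param features Feature data frame.
#' @param include_pseudogenes Translate `pseudogene` features too
#'   (default `FALSE`).
#' @param force_start_met Replace the first residue by `M` (default
#'   `FALSE`: start codons are translated as encoded, for reproducibility).
#' @return Data frame with one row per translated feature: `protein_id`
#'   (`genome_id|locus_tag`), `locus_tag`, `genome_id`, `sequence`,
#'   `disrupted`, `partial`.
#' @export
derive_proteome <- function(genome, features, include_pseudogenes = FALSE,
                            force_start_met = FALSE) {
  validate_features(genome, features)
  keep <- features$kind == "CDS" |
    (include_pseudogenes & features$kind == "pseudogene")
  f <- features[keep, , drop = FALSE]
  if (!nrow(f))
    return(data.frame(protein_id = character(), locus_tag = character(),
                      genome_id = character(), sequence = character(),
                      disrupted = logical(), partial = logical(),
                      stringsAsFactors = FALSE))
  nt <- Biostrings::DNAStringSet(lapply(seq_len(nrow(f)), function(i) {
    s <- Biostrings::subseq(genome$replicons[[f$replicon_id[i]]],
                            start = f$start[i] + 1L, end = f$end[i])
    if (f$strand[i] == "-") Biostrings::reverseComplement(s) else s
  }))
  partial <- (Biostrings::width(nt) %% 3L) != 0L
  if (any(partial)) {
    warnf("%d CDS length(s) not divisible by 3; translated on the longest in-frame prefix",
          sum(partial))
    nt[partial] <- Biostrings::subseq(
      nt[partial], 1L, (Biostrings::width(nt[partial]) %/% 3L) * 3L)
  }
  aa <- as.character(Biostrings::translate(
    nt, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve", no.init.codon = !force_start_met))
  aa <- sub("\\*$", "", aa)
  disrupted <- grepl("\\*", aa)
  aa[disrupted] <- gsub("\\*", "", aa[disrupted])  # kept for the record only
  if (force_start_met & any(nzchar(aa)))
    aa <- paste0("M", substring(aa, 2L))
  lt <- ifelse(nzchar(f$locus_tag), f$locus_tag, f$feature_id)
  data.frame(protein_id = paste(genome$genome_id, lt, sep = "|"),
             locus_tag = lt, genome_id = genome$genome_id, sequence = aa,
             disrupted = disrupted, partial = partial | f$partial,
             stringsAsFactors = FALSE)
}

# Proteins usable for similarity-based analyses (drops disrupted/empty).
clean_proteome <- function(proteome) {
  proteome[!proteome$disrupted & nzchar(proteome$sequence), , drop = FALSE]
}

#' Write a proteome to FASTA
#'
#' Headers are `genome_id|locus_tag`.
#' @param proteome Data frame from [derive_proteome()].
#' @param path Output FASTA path.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteome$sequence,
                                                proteome$protein_id))
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

#' Basic genome statistics
#'
#' @param genome A `GenomeRecord`.
#' @param features Feature data frame.
#' @return `list(length_bp, gc_percent, cds_count)`. GC% is
#'   100*(G+C)/(A+C+G+T) with `N` excluded from both numerator and
#'   denominator, reported to one decimal; `NA` for an all-N genome.
#' @export
genome_stats <- function(genome, features) {
  fr <- colSums(Biostrings::letterFrequency(genome$replicons, c("A", "C", "G", "T")))
  acgt <- sum(fr)
  gc <- if (acgt == 0) NA_real_ else round1(100 * (fr[["G"]] + fr[["C"]]) / acgt)
  list(length_bp = sum(Biostrings::width(genome$replicons)),
       gc_percent = gc,
       cds_count = sum(features$kind == "CDS"))
}
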