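# Chemotaxis gene cataloguing, operon and cluster calling, MCP heptad
# classification, cluster typing, and flagellar gene census.

CHE_KINDS <- c("cheA", "cheAY", "cheB", "cheC", "cheD", "cheR", "cheV",
               "cheW", "cheX", "cheY", "mcp")

MCP_CLASSES <- c(24L, 28L, 34L, 36L, 38L, 40L, 44L, 64L)

# Kyte-Doolittle hydropathy
KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
        G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
        P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

#' Catalog chemotaxis genes from annotation keywords
#'
#' Product strings are matched against keyword rules (fusion kinases
#' first, then methyl-accepting receptors, then `Che<letter>` names). An
#' optional user table `locus_tag -> kind` overrides the keywords. Every
#' assignment carries its evidence tag.
#'
#' @param features Feature data frame of one genome.
#' @param user_table Optional data frame `locus_tag, kind`.
#' @return Data frame `locus_tag, kind, evidence` (one row per
#'   chemotaxis gene, genome order preserved).
#' @export
catalog_che_genes <- function(features, user_table = NULL) {
  f <- features[features$kind == "CDS", , drop = FALSE]
  kind <- rep(NA_character_, nrow(f))
  p <- f$product
  fusion <- grepl("cheA[-/ ]?cheY|cheAY|cheA.*cheY.*(fusion|hybrid)", p,
                  ignore.case = TRUE)
  kind[fusion] <- "cheAY"
  mcp <- is.na(kind) & grepl("methyl[- ]accepting chemotaxis", p, ignore.case = TRUE)
  kind[mcp] <- "mcp"
  m <- regexpr("Che([ABCDRVWXY])\\b", p, ignore.case = FALSE)
  hit <- is.na(kind) & m > 0
  kind[hit] <- paste0("che", substring(p[hit], m[hit] + 3L, m[hit] + 3L))
  evidence <- ifelse(is.na(kind), NA_character_, "annotation keyword")

  if (!is.null(user_table) && nrow(user_table)) {
    dup <- user_table$locus_tag[duplicated(user_table$locus_tag) |
                                  duplicated(user_table$locus_tag, fromLast = TRUE)]
    conflict <- unique(user_table[user_table$locus_tag %in% dup, , drop = FALSE])
    if (length(unique(conflict$locus_tag)) <
        length(conflict$locus_tag))
      stopf("conflicting user-table entries for loci: %s",
            paste(unique(conflict$locus_tag), collapse = ", "))
    bad <- setdiff(user_table$kind, CHE_KINDS)
    if (length(bad)) stopf("unknown chemotaxis kind(s) in user table: %s",
                           paste(bad, collapse = ", "))
    idx <- match(user_table$locus_tag, f$locus_tag)
    ok <- !is.na(idx)
    kind[idx[ok]] <- user_table$kind[ok]
    evidence[idx[ok]] <- "user table"
  }
  keep <- !is.na(kind)
  data.frame(locus_tag = f$locus_tag[keep], kind = kind[keep],
             evidence = evidence[keep], stringsAsFactors = FALSE)
}

#' Call operons by the same-strand distance rule
#'
#' Maximal runs of consecutive same-strand genes with intergenic gaps of
#' at most `max_gap_bp`; a strand flip always breaks the run.
#'
#' @param features Feature data frame (CDS and pseudogene features are
#'   used).
#' @param max_gap_bp Maximum intergenic gap (default 200 bp).
#' @return Data frame `operon_id, replicon_id, start, end, strand,
#'   n_genes, locus_tags` (comma-separated, genome order).
#' @export
call_operons <- function(features, max_gap_bp = 200L) {
  f <- sort_features(features[features$kind != "other", , drop = FALSE])
  if (!nrow(f)) return(data.frame())
  brk <- c(TRUE, f$replicon_id[-1] != f$replicon_id[-nrow(f)] |
             f$strand[-1] != f$strand[-nrow(f)] |
             (f$start[-1] - f$end[-nrow(f)]) > max_gap_bp)
  grp <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_len(nrow(f)), grp), function(i)
    data.frame(replicon_id = f$replicon_id[i[1]], start = min(f$start[i]),
               end = max(f$end[i]), strand = f$strand[i[1]],
               n_genes = length(i),
               locus_tags = paste(f$locus_tag[i], collapse = ","),
               stringsAsFactors = FALSE)))
  out$operon_id <- sprintf("operon%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("operon_id", "replicon_id", "start", "end", "strand", "n_genes",
          "locus_tags")]
}

# generic window rule: group positions of flagged genes along the gene
# order, allowing <= max_intervening non-flagged genes between neighbours
cluster_windows <- function(flag_idx, max_intervening) {
  if (!length(flag_idx)) return(list())
  brk <- c(TRUE, diff(flag_idx) > max_intervening + 1L)
  split(flag_idx, cumsum(brk))
}

#' Detect chemotaxis gene clusters
#'
#' Maximal genomic windows in which consecutive chemotaxis genes are
#' separated by at most `max_intervening` non-chemotaxis genes; windows
#' with at least `min_che` chemotaxis genes are kept. Receptor (`mcp`)
#' genes outside every window are reported as dispersed.
#'
#' @param che_genes Catalog from [catalog_che_genes()].
#' @param features Feature data frame of the same genome.
#' @param max_intervening Maximum interleaved non-che genes (default 2).
#' @param min_che Minimum chemotaxis genes per cluster (default 3).
#' @return List with `clusters` (data frame: `cluster_id, replicon_id,
#'   start, end, n_che, che_kinds, member_locus_tags` including
#'   interleaved genes) and `dispersed_mcp` (locus tags).
#' @export
detect_che_clusters <- function(che_genes, features, max_intervening = 2L,
                                min_che = 3L) {
  f <- sort_features(features[features$kind == "CDS", , drop = FALSE])
  is_che <- f$locus_tag %in% che_genes$locus_tag
  kind_of <- stats::setNames(che_genes$kind, che_genes$locus_tag)
  rows <- list(); in_cluster <- character(0)
  for (rid in unique(f$replicon_id)) {
    ri <- which(f$replicon_id == rid)
    ci <- ri[is_che[ri]]
    for (w in cluster_windows(match(ci, ri), max_intervening)) {
      if (length(w) < min_che) next
      span <- ri[w[1]:w[length(w)]]
      tags <- f$locus_tag[span]
      che_tags <- tags[tags %in% che_genes$locus_tag]
      in_cluster <- c(in_cluster, che_tags)
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = rid, start = f$start[span[1]], end = f$end[span[length(span)]],
        n_che = length(che_tags),
        che_kinds = paste(unname(kind_of[che_tags]), collapse = ","),
        member_locus_tags = paste(tags, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon_id = character(), start = integer(), end = integer(),
               n_che = integer(), che_kinds = character(),
               member_locus_tags = character(), stringsAsFactors = FALSE)
  if (nrow(clusters)) {
    clusters$cluster_id <- sprintf("che_cluster%02d", seq_len(nrow(clusters)))
    clusters <- clusters[, c("cluster_id", "replicon_id", "start", "end",
                             "n_che", "che_kinds", "member_locus_tags")]
  }
  disp <- che_genes$locus_tag[che_genes$kind == "mcp" &
                                !che_genes$locus_tag %in% in_cluster]
  list(clusters = clusters, dispersed_mcp = disp)
}

kd_tm_regions <- function(seq, window = 19L, cutoff = 1.6) {
  kd <- unname(KD[strsplit(toupper(seq), "")[[1]]])
  kd[is.na(kd)] <- 0
  n <- length(kd)
  if (n < window) return(NULL)
  means <- (cumsum(c(kd, 0))[(window + 1):(n + 1)] -
              cumsum(c(0, kd))[1:(n - window + 1)]) / window
  starts <- which(means >= cutoff)
  if (!length(starts)) return(NULL)
  covered <- sort(unique(unlist(lapply(starts, function(s) s:(s + window - 1L)))))
  brk <- c(TRUE, diff(covered) > 1L)
  grp <- cumsum(brk)
  do.call(rbind, lapply(split(covered, grp), function(v)
    c(start = min(v), end = max(v))))
}

#' Classify an MCP by heptad count of its cytoplasmic domain
#'
#' Transmembrane helices are detected as merged Kyte-Doolittle hydropathy
#' windows (window 19, mean >= 1.6); the cytoplasmic domain is the
#' sequence C-terminal of the last helix. The heptad count is
#' `H = round(domain length / 7)` and the class is the nearest value in
#' {24, 28, 34, 36, 38, 40, 44, 64} when within 2 heptads, otherwise
#' unclassified.
#'
#' @param protein Protein sequence (character) or one-row proteome data
#'   frame.
#' @return An `McpClass` list: `protein_id, heptad_count, class`
#'   (`NA` when unclassified), `cytoplasmic_span` (1-based), `flag`
#'   (`"ok"`, `"no_tm_helix"`, `"too_short"`).
#' @export
classify_mcp <- function(protein) {
  if (is.data.frame(protein)) {
    pid <- protein$protein_id[1]; seq <- protein$sequence[1]
  } else {
    pid <- NA_character_; seq <- protein
  }
  n <- nchar(seq)
  if (n < 50L)
    return(structure(list(protein_id = pid, heptad_count = NA_integer_,
                          class = NA_integer_, cytoplasmic_span = NULL,
                          flag = "too_short"), class = "McpClass"))
  tm <- kd_tm_regions(seq)
  if (is.null(tm)) {
    H <- as.integer(round(n / 7))
    return(structure(list(protein_id = pid, heptad_count = H,
                          class = NA_integer_, cytoplasmic_span = c(1L, n),
                          flag = "no_tm_helix"), class = "McpClass"))
  }
  dom_start <- tm[nrow(tm), "end"] + 1L
  dom_len <- max(0L, n - dom_start + 1L)
  H <- as.integer(round(dom_len / 7))
  cls <- MCP_CLASSES[which.min(abs(MCP_CLASSES - H))]
  if (abs(H - cls) > 2L) cls <- NA_integer_
  structure(list(protein_id = pid, heptad_count = H, class = cls,
                 cytoplasmic_span = c(unname(dom_start), n), flag = "ok"),
            class = "McpClass")
}

#' Type a chemotaxis cluster by its gene composition
#'
#' First matching rule wins: (1) a CheA-CheY fusion gene makes the
#' cluster Frz-like; (2) a 44H receptor together with cheA, cheC, cheD,
#' cheW and cheY makes it Dif-like; (3) cheA+cheB+cheR+cheW with no
#' receptor is the Deltaproteobacteria beta group — with cheC, cheD and
#' cheX additionally present, its CDX variant; (4) two or more receptor
#' genes plus at least one interleaved non-chemotaxis gene is the E.
#' coli-like type 2; otherwise unclassified.
#'
#' @param member_kinds Character vector of chemotaxis gene kinds in the
#'   cluster.
#' @param mcp_classes Integer vector of heptad classes of the cluster's
#'   receptors (`NA` allowed).
#' @param n_interleaved Number of interleaved non-chemotaxis genes in
#'   the cluster window.
#' @return Type label: `"FrzLike"`, `"DifLike"`, `"BetaGroup"`,
#'   `"BetaCDX"`, `"EcoliLikeType2"` or `"Unclassified"`.
#' @export
type_cluster <- function(member_kinds, mcp_classes = integer(0),
                         n_interleaved = 0L) {
  has <- function(...) all(c(...) %in% member_kinds)
  n_mcp <- sum(member_kinds == "mcp")
  if (has("cheAY")) return("FrzLike")
  if (44L %in% mcp_classes && has("cheA", "cheC", "cheD", "cheW", "cheY"))
    return("DifLike")
  if (has("cheA", "cheB", "cheR", "cheW") && n_mcp == 0L) {
    if (has("cheC", "cheD", "cheX")) return("BetaCDX")
    return("BetaGroup")
  }
  if (n_mcp >= 2L && n_interleaved >= 1L) return("EcoliLikeType2")
  "Unclassified"
}

#' Full chemotaxis map of one genome
#'
#' Runs the catalog, cluster detection, receptor classification and
#' cluster typing in one pass.
#'
#' @param features Feature data frame.
#' @param proteome Proteome data frame of the same genome.
#' @param user_table,max_intervening,min_che See the stage functions.
#' @return List: `catalog`, `clusters` (with a `type` column),
#'   `dispersed_mcp`, `mcp_classes` (data frame `locus_tag, heptad_count,
#'   class, flag`), `kind_counts` (named vector over all kinds).
#' @export
map_chemotaxis <- function(features, proteome, user_table = NULL,
                           max_intervening = 2L, min_che = 3L) {
  catalog <- catalog_che_genes(features, user_table)
  det <- detect_che_clusters(catalog, features, max_intervening, min_che)
  pr <- clean_proteome(proteome)
  seq_of <- stats::setNames(pr$sequence, pr$locus_tag)
  mcp_tags <- catalog$locus_tag[catalog$kind == "mcp"]
  mcp_classes <- do.call(rbind, lapply(mcp_tags, function(lt) {
    s <- seq_of[[lt]]
    if (is.null(s)) return(data.frame(locus_tag = lt, heptad_count = NA_integer_,
                                      class = NA_integer_, flag = "no_protein",
                                      stringsAsFactors = FALSE))
    mc <- classify_mcp(s)
    data.frame(locus_tag = lt, heptad_count = mc$heptad_count,
               class = mc$class, flag = mc$flag, stringsAsFactors = FALSE)
  }))
  class_of <- if (!is.null(mcp_classes))
    stats::setNames(mcp_classes$class, mcp_classes$locus_tag) else integer(0)
  cl <- det$clusters
  if (nrow(cl)) {
    cl$type <- vapply(seq_len(nrow(cl)), function(i) {
      members <- strsplit(cl$member_locus_tags[i], ",")[[1]]
      che_tags <- members[members %in% catalog$locus_tag]
      kinds <- catalog$kind[match(che_tags, catalog$locus_tag)]
      mcls <- unname(class_of[che_tags[kinds == "mcp"]])
      type_cluster(kinds, mcls[!is.na(mcls)],
                   n_interleaved = length(members) - length(che_tags))
    }, character(1))
  }
  kind_counts <- table(factor(catalog$kind, CHE_KINDS))
  list(catalog = catalog, clusters = cl, dispersed_mcp = det$dispersed_mcp,
       mcp_classes = mcp_classes,
       kind_counts = stats::setNames(as.integer(kind_counts), CHE_KINDS))
}

FLAGELLAR_KEYWORDS <- "flagell|\\bflg[A-Z]|\\bfli[A-Z]|\\bflh[A-Z]|\\bmot[A-Z]"

#' Census of flagellar biosynthesis genes
#'
#' Flagellar genes are identified by gene-name/product prefixes
#' (flg/flh/fli/mot/flagell*); loci are windows under the same rule as
#' chemotaxis clusters (at most `max_intervening` interleaved genes); the
#' cluster is called complete when the largest locus holds at least
#' `complete_min` flagellar genes.
#'
#' @param features Feature data frame.
#' @param max_intervening Maximum interleaved non-flagellar genes.
#' @param complete_min Genes required in one locus to call the cluster
#'   complete (default 25).
#' @return List `n_flagellar_genes, n_loci, largest_locus, complete`.
#' @export
flagellar_census <- function(features, max_intervening = 2L,
                             complete_min = 25L) {
  f <- sort_features(features[features$kind == "CDS", , drop = FALSE])
  is_fla <- grepl(FLAGELLAR_KEYWORDS, f$product, ignore.case = TRUE)
  loci <- list()
  for (rid in unique(f$replicon_id)) {
    ri <- which(f$replicon_id == rid)
    fi <- match(ri[is_fla[ri]], ri)
    loci <- c(loci, cluster_windows(fi, max_intervening))
  }
  sizes <- lengths(loci)
  list(n_flagellar_genes = sum(is_fla), n_loci = length(loci),
       largest_locus = if (length(sizes)) max(sizes) else 0L,
       complete = length(sizes) > 0 && max(sizes) >= complete_min)
}
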