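# Deterministic simulator of annotated bacterial genome sets with planted
# signature features (multiheme cytochromes, MCPs of chosen heptad class,
# chemotaxis operons of each architecture, transposase copies, a flagellar
# cluster) and a machine-readable truth table.

BASES <- c("A", "C", "G", "T")

CHE_PRODUCTS <- c(
  cheA = "chemotaxis protein CheA",
  cheAY = "CheA-CheY fusion protein",
  cheB = "chemotaxis response regulator protein-glutamate methylesterase CheB",
  cheC = "chemotaxis protein CheC",
  cheD = "chemotaxis protein CheD",
  cheR = "chemotaxis protein methyltransferase CheR",
  cheV = "chemotaxis protein CheV",
  cheW = "purine-binding chemotaxis protein CheW",
  cheX = "chemotaxis protein CheX",
  cheY = "chemotaxis response regulator CheY",
  mcp = "methyl-accepting chemotaxis protein")

# Gene composition of each chemotaxis cluster architecture. "mcp:<H>"
# denotes a receptor of the given heptad class; "neutral" an interleaved
# non-chemotaxis gene (the E. coli-like type 2 hallmark).
CHE_OPERON_PLANS <- list(
  FrzLike = c("cheAY", "cheB", "cheR", "cheW", "mcp:40"),
  DifLike = c("cheA", "cheC", "cheD", "cheW", "cheY", "mcp:44"),
  BetaGroup = c("cheA", "cheB", "cheR", "cheW", "cheY"),
  BetaCDX = c("cheA", "cheB", "cheR", "cheW", "cheC", "cheD", "cheX"),
  EcoliLikeType2 = c("cheA", "cheB", "cheR", "cheW", "mcp:36", "neutral", "mcp:36"))

FLAGELLAR_PRODUCTS <- c(
  "flagellar basal-body rod protein FlgB", "flagellar basal-body rod protein FlgC",
  "flagellar hook-basal body protein FliE", "flagellar M-ring protein FliF",
  "flagellar motor switch protein FliG", "flagellar assembly protein FliH",
  "flagellum-specific ATP synthase FliI", "flagellar hook protein FlgE",
  "flagellar motor stator protein MotA", "flagellar motor stator protein MotB",
  "flagellar hook-associated protein FlgK", "flagellar hook-associated protein FlgL",
  "flagellin FliC", "flagellar cap protein FliD", "flagellar protein FliS",
  "flagellar basal body P-ring protein FlgI", "flagellar L-ring protein FlgH",
  "flagellar biosynthesis protein FlhA", "flagellar biosynthesis protein FlhB",
  "flagellar biosynthesis protein FliP", "flagellar biosynthesis protein FliQ",
  "flagellar biosynthesis protein FliR", "flagellar hook-length control protein FliK",
  "flagellar basal body rod modification protein FlgD",
  "flagellar motor switch protein FliM", "flagellar motor switch protein FliN",
  "flagellar brake protein YcgR", "flagellar regulator FlhF",
  "flagellar biosynthesis repressor FlbT", "flagellar P-ring protein precursor FlgA")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# codon -> aa for table 11, stops excluded; built once at load
codon_table11 <- local({
  gc <- Biostrings::getGeneticCode("11")
  gc[gc != "*"]
})

codon_gc_weight <- function(codons, gc_target) {
  pb <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
          G = gc_target / 2, T = (1 - gc_target) / 2)
  vapply(strsplit(codons, ""), function(b) prod(pb[b]), numeric(1))
}

# Reverse-translate a protein, drawing synonymous codons with probabilities
# proportional to their likelihood under i.i.d. bases at the target GC, so
# coding GC tracks the genome-wide target as closely as the amino-acid
# sequence allows.
reverse_translate <- function(aa, gc_target) {
  by_aa <- split(names(codon_table11), codon_table11)
  w_aa <- lapply(by_aa, codon_gc_weight, gc_target = gc_target)
  chars <- strsplit(aa, "")[[1]]
  codons <- vapply(chars, function(a) {
    cands <- by_aa[[a]]
    if (is.null(cands)) stopf("cannot reverse-translate residue '%s'", a)
    if (length(cands) == 1L) return(cands)
    sample(cands, 1L, prob = w_aa[[a]])
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), "TAA")
}

# Stop-free random codon sequence of n_aa codons drawn i.i.d. at the
# target GC (stop codons resampled), so generic genes carry the genome's
# base composition. Returns list(nt, protein).
random_codon_gene <- function(n_aa, gc_target) {
  draw <- function(n) {
    v <- sample(BASES, 3L * n, replace = TRUE,
                prob = c((1 - gc_target) / 2, gc_target / 2,
                         gc_target / 2, (1 - gc_target) / 2))
    paste0(v[seq(1L, 3L * n, 3L)], v[seq(2L, 3L * n, 3L)], v[seq(3L, 3L * n, 3L)])
  }
  codons <- draw(n_aa)
  repeat {
    bad <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(bad)) break
    codons[bad] <- draw(length(bad))
  }
  list(nt = paste0(paste(codons, collapse = ""), "TAA"),
       protein = paste(codon_table11[codons], collapse = ""))
}

random_dna <- function(n, gc_target) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc_target) / 2, gc_target / 2,
                        gc_target / 2, (1 - gc_target) / 2)), collapse = "")
}

random_protein <- function(n) {
  paste0("M", paste(sample(AA20, n - 1L, replace = TRUE), collapse = ""))
}

#' Construct a protein with exactly k heme-binding CXXCH motifs
#'
#' The background alphabet excludes C and H, so the only matches of either
#' heme-motif pattern mode are the planted motifs: an unambiguous oracle
#' for the motif scanner.
#'
#' @param k_motifs Number of planted C-X-X-C-H motifs.
#' @param length_aa Approximate protein length.
#' @return Protein sequence (character scalar).
#' @export
make_cytochrome_protein <- function(k_motifs, length_aa = 150L) {
  bg_alpha <- setdiff(AA20, c("C", "H", "M"))
  bg <- function(n) paste(sample(bg_alpha, n, replace = TRUE), collapse = "")
  need <- 1L + k_motifs * 5L
  if (length_aa < need + k_motifs * 4L + 8L)
    length_aa <- need + k_motifs * 4L + 8L
  spare <- length_aa - need
  gaps <- rep(spare %/% (k_motifs + 1L), k_motifs + 1L)
  gaps[1] <- gaps[1] + spare %% (k_motifs + 1L)
  parts <- character(0)
  for (i in seq_len(k_motifs)) parts <- c(parts, bg(gaps[i]), "CAACH")
  paste0("M", paste(c(parts, bg(gaps[k_motifs + 1L])), collapse = ""))
}

# Hydrophobic stretch tuned so Kyte-Doolittle window-19 means are >= 1.6
# only for windows lying entirely inside the stretch (A/M alternation,
# mean KD 1.85); flanks use strongly hydrophilic residues (KD <= -3.5).
MCP_TM <- paste(rep(c("A", "M"), 10L), collapse = "")
MCP_HYDROPHILIC <- c("D", "E", "K", "R", "N", "Q")

#' Construct a methyl-accepting chemotaxis protein of a given heptad class
#'
#' Layout: Met + 24-residue hydrophilic N-terminal segment + 20-residue
#' transmembrane stretch + 10-residue periplasmic loop + second
#' transmembrane stretch + hydrophilic cytoplasmic tail of exactly
#' `7 * class_H` residues, making the hydropathy-based classifier's
#' assumptions literal.
#'
#' @param class_H Heptad class, one of 24, 28, 34, 36, 38, 40, 44, 64.
#' @return Protein sequence (character scalar).
#' @export
make_mcp_protein <- function(class_H) {
  if (!class_H %in% MCP_CLASSES) stopf("invalid MCP class %s", class_H)
  hyd <- function(n) paste(sample(MCP_HYDROPHILIC, n, replace = TRUE), collapse = "")
  paste0("M", hyd(24L), MCP_TM, hyd(10L), MCP_TM, hyd(7L * class_H))
}

transposase_seed_protein <- function(family, length_aa = 120L) {
  with_rng(sum(utf8ToInt(family)) * 131L + 7L, random_protein(length_aa))
}

#' Declare a feature to plant in simulated genomes
#'
#' @param role One of `"cytochrome"`, `"mcp"`, `"che_operon"`,
#'   `"transposase"`, `"flagellar_cluster"`, `"neutral"`.
#' @param targets Integer indices of the genomes carrying the feature
#'   (`NULL` = all genomes).
#' @param k_motifs Heme motifs per cytochrome.
#' @param class_H MCP heptad class.
#' @param type Chemotaxis cluster architecture (see `CHE_OPERON_PLANS`).
#' @param family IS family label for a transposase.
#' @param copies Number of transposase copies.
#' @param n_genes Genes in a flagellar cluster.
#' @return A `PlantSpec` list.
#' @export
plant_spec <- function(role, targets = NULL, k_motifs = 4L, class_H = 36L,
                       type = "FrzLike", family = "IS3", copies = 1L,
                       n_genes = 30L) {
  role <- match.arg(role, c("cytochrome", "mcp", "che_operon", "transposase",
                            "flagellar_cluster", "neutral"))
  if (role == "che_operon" && !type %in% names(CHE_OPERON_PLANS))
    stopf("unknown chemotaxis cluster type '%s'", type)
  if (role == "mcp" && !class_H %in% MCP_CLASSES)
    stopf("invalid MCP class %s", class_H)
  if (role == "cytochrome" && k_motifs < 0) stopf("k_motifs must be >= 0")
  structure(list(role = role, targets = targets, k_motifs = k_motifs,
                 class_H = class_H, type = type, family = family,
                 copies = copies, n_genes = n_genes), class = "PlantSpec")
}

#' Default feature plan mirroring the study design
#'
#' Five chemotaxis cluster architectures; dispersed receptors of classes
#' 24/34/36/40/44/64 (36H restricted to the first two genomes, as in the
#' iron/sulfur-stimulated strains); multiheme cytochromes shared by all,
#' by the first two, or by the remaining genomes (the two-block profile);
#' transposase expansion in the later genomes; a complete flagellar
#' cluster in the first two genomes.
#'
#' @param n_genomes Number of genomes in the set.
#' @return List of `PlantSpec`s.
#' @export
default_feature_plan <- function(n_genomes = 5L) {
  g12 <- seq_len(min(2L, n_genomes))
  g_rest <- if (n_genomes > 2L) 3:n_genomes else g12
  list(
    plant_spec("flagellar_cluster", targets = g12, n_genes = 30L),
    plant_spec("che_operon", type = "FrzLike", targets = g12),
    plant_spec("che_operon", type = "DifLike"),
    plant_spec("che_operon", type = "BetaGroup"),
    plant_spec("che_operon", type = "BetaCDX", targets = g12),
    plant_spec("che_operon", type = "EcoliLikeType2"),
    plant_spec("mcp", class_H = 24L), plant_spec("mcp", class_H = 34L),
    plant_spec("mcp", class_H = 36L, targets = g12),
    plant_spec("mcp", class_H = 40L), plant_spec("mcp", class_H = 44L),
    plant_spec("mcp", class_H = 64L),
    plant_spec("cytochrome", k_motifs = 10L),
    plant_spec("cytochrome", k_motifs = 12L),
    plant_spec("cytochrome", k_motifs = 9L, targets = g12),
    plant_spec("cytochrome", k_motifs = 14L, targets = g_rest),
    plant_spec("transposase", family = "IS3", copies = 3L, targets = g_rest),
    plant_spec("transposase", family = "IS256", copies = 2L, targets = g_rest),
    plant_spec("transposase", family = "IS110", copies = 1L))
}

#' Simulation configuration
#'
#' @param seed Master seed; fully determines all outputs.
#' @param n_genomes Number of genomes (ancestor plus evolved siblings).
#' @param genome_length_bp Target genome length.
#' @param gene_count Total genes per genome (planted + neutral filler).
#' @param gc_target Genome-wide GC fraction.
#' @param substitution_rate Per-site, per-branch substitution probability
#'   (single hit per site), in `[0, 0.75]`.
#' @param indel_rate Per-site indel initiation probability (intergenic
#'   sequence only; coding regions are indel-protected so planted role
#'   parameters survive).
#' @param feature_plan List of [plant_spec()]s; default
#'   [default_feature_plan()].
#' @param neutral_protein_aa Length of neutral filler proteins.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L, n_genomes = 5L, genome_length_bp = 70000L,
                       gene_count = 110L, gc_target = 0.58,
                       substitution_rate = 0.05, indel_rate = 0,
                       feature_plan = NULL, neutral_protein_aa = 150L) {
  if (substitution_rate < 0 || substitution_rate > 0.75)
    stopf("substitution_rate must be in [0, 0.75]")
  if (gc_target <= 0 || gc_target >= 1) stopf("gc_target must be in (0,1)")
  if (n_genomes < 1) stopf("need at least one genome")
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 genome_length_bp = as.integer(genome_length_bp),
                 gene_count = as.integer(gene_count), gc_target = gc_target,
                 substitution_rate = substitution_rate, indel_rate = indel_rate,
                 feature_plan = feature_plan %||% default_feature_plan(n_genomes),
                 neutral_protein_aa = as.integer(neutral_protein_aa)),
            class = "SimulationConfig")
}

# Expand the feature plan into an ordered list of gene specifications:
# chemotaxis items separated by >= 3 universal neutral genes so cluster
# detection boundaries are unambiguous in every genome; genes with
# restricted targets go at the tail so their absence never merges
# chemotaxis clusters.
expand_plan <- function(config) {
  plan <- config$feature_plan
  all_targets <- seq_len(config$n_genomes)
  gene <- function(role, product, targets, param = "", cluster = NA_character_,
                   protein_len = config$neutral_protein_aa, kindof = "single")
    list(role = role, product = product,
         targets = targets %||% all_targets, param = param,
         cluster = cluster, protein_len = protein_len, kindof = kindof)

  che_items <- list(); tail_items <- list(); flag_block <- list()
  n_op <- 0L
  for (ps in plan) {
    tg <- ps$targets %||% all_targets
    universal <- setequal(tg, all_targets)
    switch(ps$role,
      flagellar_cluster = {
        flag_block <- lapply(seq_len(ps$n_genes), function(i)
          gene("flagellar", FLAGELLAR_PRODUCTS[((i - 1L) %% length(FLAGELLAR_PRODUCTS)) + 1L],
               tg, cluster = "flagellar", protein_len = 100L, kindof = "block"))
      },
      che_operon = {
        n_op <<- n_op + 1L
        cl <- sprintf("che_%s_%d", ps$type, n_op)
        members <- CHE_OPERON_PLANS[[ps$type]]
        ops <- lapply(members, function(m) {
          if (m == "neutral")
            gene("neutral", "hypothetical protein", tg,
                 param = sprintf("type=%s", ps$type), cluster = cl, kindof = "block")
          else if (startsWith(m, "mcp"))
            gene("mcp", CHE_PRODUCTS[["mcp"]], tg,
                 param = sprintf("H=%s;type=%s", sub("mcp:", "", m), ps$type),
                 cluster = cl, kindof = "block")
          else
            gene(m, CHE_PRODUCTS[[m]], tg,
                 param = sprintf("type=%s", ps$type), cluster = cl,
                 protein_len = 120L, kindof = "block")
        })
        che_items[[length(che_items) + 1L]] <- ops
      },
      mcp = che_items[[length(che_items) + 1L]] <-
        list(gene("mcp", CHE_PRODUCTS[["mcp"]], tg,
                  param = sprintf("H=%d", ps$class_H))),
      cytochrome = {
        it <- gene("cytochrome", "cytochrome c family protein", tg,
                   param = sprintf("k=%d", ps$k_motifs))
        if (universal) tail_items[[length(tail_items) + 1L]] <- it
        else tail_items[[length(tail_items) + 1L]] <- it
      },
      transposase = {
        for (i in seq_len(ps$copies))
          tail_items[[length(tail_items) + 1L]] <-
            gene("transposase", sprintf("%s family transposase", ps$family),
                 tg, param = sprintf("family=%s;copy=%d", ps$family, i),
                 protein_len = 120L)
      },
      neutral = tail_items[[length(tail_items) + 1L]] <-
        gene("neutral", "hypothetical protein", tg))
  }

  n_planted <- length(flag_block) + sum(lengths(che_items)) + length(tail_items)
  n_neutral <- config$gene_count - n_planted
  n_gaps <- max(0L, length(che_items) - 1L)
  if (n_neutral < 3L * n_gaps + 3L)
    stopf("gene_count %d too small for the feature plan (need >= %d)",
          config$gene_count, n_planted + 3L * n_gaps + 3L)
  neutral_gene <- function() gene("neutral", "hypothetical protein", all_targets)

  ordered <- flag_block
  used_neutral <- 0L
  for (i in seq_along(che_items)) {
    if (i > 1L) {
      for (j in 1:3) ordered[[length(ordered) + 1L]] <- neutral_gene()
      used_neutral <- used_neutral + 3L
    }
    ordered <- c(ordered, che_items[[i]])
  }
  # buffer before the differential tail keeps the last chemotaxis item
  # separated from everything downstream
  for (j in 1:3) ordered[[length(ordered) + 1L]] <- neutral_gene()
  used_neutral <- used_neutral + 3L
  ordered <- c(ordered, tail_items)
  while (used_neutral < n_neutral) {
    ordered[[length(ordered) + 1L]] <- neutral_gene()
    used_neutral <- used_neutral + 1L
  }
  ordered
}

#' Simulate the ancestral annotated genome
#'
#' Builds one genome containing every planted feature of the plan (target
#' subsets are applied when siblings are derived), with intergenic
#' sequence i.i.d. at the target GC and genes as stop-free codon
#' sequences. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param genome_id Label for the ancestor.
#' @return `list(genome, features, truth_genes)`; `truth_genes` records
#'   locus tag, family id, role, role parameters, cluster id and target
#'   genome indices of every gene.
#' @export
simulate_ancestor <- function(config, genome_id = "ANC") {
  with_rng(config$seed, {
    specs <- expand_plan(config)
    n <- length(specs)
    proteins <- character(n); nts <- character(n)
    for (i in seq_len(n)) {
      sp <- specs[[i]]
      # motif-bearing roles are built protein-first (exact oracle), all
      # other genes nucleotide-first at the target base composition
      if (sp$role %in% c("cytochrome", "mcp", "transposase")) {
        proteins[i] <- switch(sp$role,
          cytochrome = make_cytochrome_protein(
            as.integer(sub("k=", "", sp$param)), config$neutral_protein_aa),
          mcp = make_mcp_protein(as.integer(sub("H=(\\d+).*", "\\1", sp$param))),
          transposase = {
            fam <- sub("family=([^;]+).*", "\\1", sp$param)
            cp <- as.integer(sub(".*copy=", "", sp$param))
            seed_prot <- transposase_seed_protein(fam)
            # copies carry slight mutual divergence so orthologs of each
            # copy remain distinguishable while family identity is kept
            if (cp > 1L) evolve_protein_sequence(seed_prot, 0.1 * (cp - 1L))
            else seed_prot
          })
        nts[i] <- reverse_translate(proteins[i], config$gc_target)
      } else {
        g <- random_codon_gene(sp$protein_len, config$gc_target)
        proteins[i] <- g$protein
        nts[i] <- g$nt
      }
    }
    glen <- nchar(nts)
    # within-block neighbours sit 50 bp apart (operon-callable); the rest
    # of the length budget spreads over the remaining gaps
    in_block <- vapply(seq_len(n), function(i)
      i > 1L && specs[[i]]$kindof == "block" && specs[[i - 1L]]$kindof == "block" &&
        identical(specs[[i]]$cluster, specs[[i - 1L]]$cluster), logical(1))
    n_small <- sum(in_block)
    budget <- config$genome_length_bp - sum(glen) - 50L * n_small
    n_big <- n + 1L - n_small
    if (budget < 30L * n_big)
      stopf("feature plan does not fit in genome_length_bp=%d", config$genome_length_bp)
    big_gap <- budget %/% n_big

    pieces <- character(2L * n + 1L)
    starts <- integer(n); pos <- 0L
    for (i in seq_len(n)) {
      gap_i <- if (in_block[i]) 50L else big_gap
      pieces[2L * i - 1L] <- random_dna(gap_i, config$gc_target)
      pos <- pos + gap_i
      starts[i] <- pos
      pieces[2L * i] <- nts[i]
      pos <- pos + glen[i]
    }
    tail_len <- config$genome_length_bp - pos
    pieces[2L * n + 1L] <- if (tail_len > 0) random_dna(tail_len, config$gc_target) else ""
    seq_chr <- paste(pieces, collapse = "")

    strand <- character(n); blk_strand <- "+"
    last_cluster <- ""
    alt <- TRUE
    for (i in seq_len(n)) {
      sp <- specs[[i]]
      if (sp$kindof == "block") {
        if (!identical(sp$cluster, last_cluster)) blk_strand <- "+"
        strand[i] <- blk_strand
        last_cluster <- sp$cluster %||% ""
      } else {
        strand[i] <- if (alt) "+" else "-"
        alt <- !alt
      }
    }
    lt <- sprintf("%s_%04d", genome_id, seq_len(n))
    feats <- data.frame(
      feature_id = lt, replicon_id = "chr", start = starts,
      end = starts + glen, strand = strand, kind = "CDS",
      product = vapply(specs, `[[`, "", "product"),
      locus_tag = lt, partial = FALSE, stringsAsFactors = FALSE)
    # minus-strand genes: store the reverse complement so the annotated
    # protein is the designed one
    for (i in which(strand == "-")) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nts[i])))
      seq_chr <- paste0(substr(seq_chr, 1L, starts[i]), rc,
                        substr(seq_chr, starts[i] + glen[i] + 1L, nchar(seq_chr)))
    }
    genome <- genome_record(genome_id, stats::setNames(
      Biostrings::DNAStringSet(seq_chr), "chr"), assembly_level = "complete")
    truth_genes <- data.frame(
      genome_id = genome_id, locus_tag = lt,
      family_id = sprintf("F%04d", seq_len(n)),
      role = vapply(specs, `[[`, "", "role"),
      param = vapply(specs, `[[`, "", "param"),
      cluster_id = vapply(specs, function(s) s$cluster %||% NA_character_, ""),
      targets = vapply(specs, function(s) paste(s$targets, collapse = ","), ""),
      protein = proteins, stringsAsFactors = FALSE)
    validate_features(genome, feats)
    list(genome = genome, features = sort_features(feats), truth_genes = truth_genes)
  })
}

#' Evolve a genome along one branch
#'
#' Each site substitutes with probability `p` (one hit per site, new base
#' uniform over the three alternatives), so the realized mismatch fraction
#' against the parent equals `p` up to binomial noise. Indels (length
#' 1-10, geometric) initiate at `indel_rate` per intergenic site; coding
#' regions are indel-protected so planted role parameters survive. Genes
#' whose locus tags are in `drop_locus_tags` are excised.
#'
#' @param parent Parent `GenomeRecord`.
#' @param parent_features Parent feature table.
#' @param p Substitution probability per site, in `[0, 0.75]`.
#' @param indel_rate Indel initiation probability per intergenic site.
#' @param seed Seed for this branch.
#' @param genome_id Child genome id (locus tags are re-prefixed).
#' @param drop_locus_tags Parent locus tags absent from this child.
#' @return `list(genome, features, locus_map)` where `locus_map` maps
#'   parent to child locus tags.
#' @export
evolve_genome <- function(parent, parent_features, p, indel_rate = 0,
                          seed = 1L, genome_id = paste0(parent$genome_id, "_d"),
                          drop_locus_tags = character(0)) {
  if (p < 0 || p > 0.75) stopf("p must be in [0, 0.75]")
  with_rng(seed, {
    new_reps <- list(); new_feats <- list()
    for (rep_id in names(parent$replicons)) {
      chars <- strsplit(as.character(parent$replicons[[rep_id]]), "")[[1]]
      L <- length(chars)
      parent_chars <- chars
      if (p > 0) {
        hit <- which(stats::runif(L) < p)
        if (length(hit)) {
          cur <- match(chars[hit], BASES)
          chars[hit] <- BASES[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
        }
      }
      f <- parent_features[parent_features$replicon_id == rep_id, , drop = FALSE]
      # crude purifying selection: substitutions that create an in-frame
      # internal stop codon are reverted, so coding genes stay intact
      if (p > 0) for (i in seq_len(nrow(f))) {
        if (f$kind[i] != "CDS") next
        span <- (f$start[i] + 1L):f$end[i]
        g <- chars[span]
        if (f$strand[i] == "-")
          g <- rev(c(A = "T", C = "G", G = "C", T = "A")[g])
        nc <- length(g) %/% 3L
        if (nc < 2L) next
        cod <- paste0(g[seq(1L, 3L * nc, 3L)], g[seq(2L, 3L * nc, 3L)],
                      g[seq(3L, 3L * nc, 3L)])
        bad <- which(cod[-nc] %in% c("TAA", "TAG", "TGA"))
        for (b in bad) {
          cpos <- (3L * (b - 1L) + 1L):(3L * b)
          gpos <- if (f$strand[i] == "-") rev(length(g) + 1L - cpos) else cpos
          chars[span[gpos]] <- parent_chars[span[gpos]]
        }
      }
      f <- f[order(f$start), , drop = FALSE]
      keep <- !(f$locus_tag %in% drop_locus_tags)
      segs <- character(0); seg_is_gene <- logical(0); seg_feat <- integer(0)
      pos <- 0L
      for (i in seq_len(nrow(f))) {
        if (f$start[i] > pos) {
          segs <- c(segs, paste(chars[(pos + 1L):f$start[i]], collapse = ""))
          seg_is_gene <- c(seg_is_gene, FALSE); seg_feat <- c(seg_feat, NA_integer_)
        }
        if (keep[i]) {
          segs <- c(segs, paste(chars[(f$start[i] + 1L):f$end[i]], collapse = ""))
          seg_is_gene <- c(seg_is_gene, TRUE); seg_feat <- c(seg_feat, i)
        }
        pos <- max(pos, f$end[i])
      }
      if (pos < L) {
        segs <- c(segs, paste(chars[(pos + 1L):L], collapse = ""))
        seg_is_gene <- c(seg_is_gene, FALSE); seg_feat <- c(seg_feat, NA_integer_)
      }
      if (indel_rate > 0) {
        for (k in which(!seg_is_gene)) segs[k] <- apply_indels(segs[k], indel_rate)
      }
      out_pos <- 0L; rows <- list()
      for (k in seq_along(segs)) {
        if (seg_is_gene[k]) {
          i <- seg_feat[k]
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = NA_character_, replicon_id = rep_id, start = out_pos,
            end = out_pos + nchar(segs[k]), strand = f$strand[i],
            kind = f$kind[i], product = f$product[i],
            locus_tag = f$locus_tag[i], partial = f$partial[i],
            stringsAsFactors = FALSE)
        }
        out_pos <- out_pos + nchar(segs[k])
      }
      new_reps[[rep_id]] <- paste(segs, collapse = "")
      if (length(rows)) new_feats[[rep_id]] <- do.call(rbind, rows)
    }
    feats <- if (length(new_feats)) do.call(rbind, new_feats) else empty_features()
    old_tags <- feats$locus_tag
    idx <- sub("^[^_]*_", "", old_tags)
    feats$locus_tag <- sprintf("%s_%s", genome_id, idx)
    feats$feature_id <- feats$locus_tag
    rownames(feats) <- NULL
    genome <- genome_record(genome_id, stats::setNames(
      Biostrings::DNAStringSet(unlist(new_reps)), names(new_reps)),
      assembly_level = parent$assembly_level)
    validate_features(genome, feats)
    list(genome = genome, features = sort_features(feats),
         locus_map = stats::setNames(feats$locus_tag, old_tags))
  })
}

apply_indels <- function(seg, indel_rate) {
  L <- nchar(seg)
  ev <- which(stats::runif(L) < indel_rate)
  if (!length(ev)) return(seg)
  chars <- strsplit(seg, "")[[1]]
  out <- character(0); pos <- 1L
  for (e in ev) {
    if (e < pos) next
    out <- c(out, chars[pos:e])
    len <- min(stats::rgeom(1L, 0.5) + 1L, 10L)
    if (stats::runif(1L) < 0.5) {
      out <- c(out, sample(BASES, len, replace = TRUE))
      pos <- e + 1L
    } else {
      pos <- min(e + len, L) + 1L
    }
  }
  if (pos <= L) out <- c(out, chars[pos:L])
  paste(out, collapse = "")
}

#' Evolve a protein sequence by point substitution
#'
#' Each residue substitutes with probability `p` to a uniformly drawn
#' different residue. Used to simulate alignment columns along a known
#' tree.
#'
#' @param aa Protein sequence.
#' @param p Per-residue substitution probability.
#' @param seed Optional seed.
#' @return Mutated protein sequence.
#' @export
evolve_protein_sequence <- function(aa, p, seed = NULL) {
  with_rng(seed, {
    chars <- strsplit(aa, "")[[1]]
    hit <- which(stats::runif(length(chars)) < p)
    for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
    paste(chars, collapse = "")
  })
}

# Exact expected mismatch fraction between two genomes that diverged from
# a common ancestor along branches with single-hit rates pa and pb.
expected_pair_mismatch <- function(pa, pb) pa + pb - (4 / 3) * pa * pb

#' Simulate a full genome set with truth table
#'
#' Genome `G1` is the ancestor itself (branch length 0); genomes
#' `G2..Gn` are evolved independently at `config$substitution_rate` per
#' branch. Target subsets of the feature plan are applied by excising
#' non-target genes from the corresponding siblings.
#'
#' @param config A [sim_config()].
#' @return `list(genomes, features, truth)`: named lists per genome plus a
#'   `TruthTable` with per-gene records and the expected pairwise
#'   nucleotide identity matrix.
#' @export
simulate_genome_set <- function(config) {
  anc <- simulate_ancestor(config)
  ids <- sprintf("G%d", seq_len(config$n_genomes))
  branch_p <- c(0, rep(config$substitution_rate, config$n_genomes - 1L))
  names(branch_p) <- ids
  genomes <- list(); features <- list(); truth_rows <- list()
  for (i in seq_len(config$n_genomes)) {
    tg_keep <- vapply(strsplit(anc$truth_genes$targets, ","), function(v)
      as.character(i) %in% v, logical(1))
    drop <- anc$truth_genes$locus_tag[!tg_keep]
    ev <- evolve_genome(anc$genome, anc$features, p = branch_p[i],
                        indel_rate = config$indel_rate,
                        seed = derive_seed(config$seed, i),
                        genome_id = ids[i], drop_locus_tags = drop)
    genomes[[ids[i]]] <- ev$genome
    features[[ids[i]]] <- ev$features
    tg <- anc$truth_genes[tg_keep, , drop = FALSE]
    tg$genome_id <- ids[i]
    tg$locus_tag <- unname(ev$locus_map[tg$locus_tag])
    truth_rows[[ids[i]]] <- tg
  }
  eid <- matrix(100, config$n_genomes, config$n_genomes,
                dimnames = list(ids, ids))
  for (a in seq_len(config$n_genomes)) for (b in seq_len(config$n_genomes))
    if (a != b)
      eid[a, b] <- 100 * (1 - expected_pair_mismatch(branch_p[a], branch_p[b]))
  truth <- structure(list(genes = do.call(rbind, truth_rows),
                          expected_identity = eid, branch_p = branch_p,
                          config = config), class = "TruthTable")
  list(genomes = genomes, features = features, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Per-genome FASTA + GFF3 plus the truth table as JSON and TSV.
#'
#' @param dataset Result of [simulate_genome_set()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written paths.
#' @export
emit_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)
  paths <- character(0)
  for (gid in names(dataset$genomes)) {
    fa <- file.path(out_dir, paste0(gid, ".fna"))
    gff <- file.path(out_dir, paste0(gid, ".gff3"))
    write_annotated_genome(dataset$genomes[[gid]], dataset$features[[gid]], fa, gff)
    paths[paste0(gid, ".fna")] <- fa
    paths[paste0(gid, ".gff3")] <- gff
  }
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    genes = dataset$truth$genes[, setdiff(names(dataset$truth$genes), "protein")],
    expected_identity = as.data.frame(dataset$truth$expected_identity),
    branch_p = as.list(dataset$truth$branch_p)), tj, digits = NA, pretty = TRUE)
  tt <- file.path(out_dir, "truth.tsv")
  utils::write.table(dataset$truth$genes, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth.json"] <- tj
  paths["truth.tsv"] <- tt
  paths
}

#' Labeled transposase reference library from a truth table
#'
#' Builds the family-tagged protein FASTA records (as an `AAStringSet`)
#' from the transposase seed proteins of the planted families, for use
#' with [assign_is_family()].
#'
#' @param families Character vector of family labels.
#' @return Named `AAStringSet`; names carry `family=` tags.
#' @export
is_reference_library <- function(families = c("IS3", "IS4", "IS256",
                                              "IS200/IS605", "IS21", "IS110",
                                              "IS1595")) {
  seqs <- vapply(families, transposase_seed_protein, character(1))
  Biostrings::AAStringSet(stats::setNames(
    seqs, sprintf("%s_tnp family=%s", gsub("/", "-", families), families)))
}
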