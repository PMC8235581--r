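# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small feature plan: one operon of each chemotaxis architecture is not
# needed everywhere; this trimmed plan keeps all-vs-all affordable
small_plan <- function() {
  list(plant_spec("che_operon", type = "FrzLike"),
       plant_spec("mcp", class_H = 36L),
       plant_spec("cytochrome", k_motifs = 9L),
       plant_spec("cytochrome", k_motifs = 7L, targets = 1:2),
       plant_spec("transposase", family = "IS3", copies = 2L),
       plant_spec("transposase", family = "IS110", copies = 1L))
}

small_dataset <- function() cached("small_ds", function() {
  simulate_genome_set(sim_config(seed = 401L, n_genomes = 3L,
                                 genome_length_bp = 30000L, gene_count = 30L,
                                 gc_target = 0.55, substitution_rate = 0.05,
                                 feature_plan = small_plan()))
})

small_proteomes <- function() cached("small_prot", function() {
  ds <- small_dataset()
  stats::setNames(lapply(names(ds$genomes), function(g)
    derive_proteome(ds$genomes[[g]], ds$features[[g]])), names(ds$genomes))
})

small_hits <- function() cached("small_hits", function()
  all_vs_all(small_proteomes()))

small_rbh <- function() cached("small_rbh", function()
  build_rbh_all(small_hits()))

small_ogset <- function() cached("small_ogset", function()
  cluster_ogs(small_rbh(), small_hits(), small_proteomes()))

# default-plan single genome (all five cluster types, flagellar cluster)
rich_genome <- function() cached("rich", function() {
  ds <- simulate_genome_set(sim_config(seed = 402L, n_genomes = 1L,
                                       substitution_rate = 0))
  list(genome = ds$genomes$G1, features = ds$features$G1,
       proteome = derive_proteome(ds$genomes$G1, ds$features$G1),
       truth = ds$truth)
})

# plain 50-kb gene-light ancestor for nucleotide-level tests
flat_ancestor <- function(seed = 501L, len = 50000L) {
  simulate_ancestor(sim_config(seed = seed, n_genomes = 1L,
                               genome_length_bp = len, gene_count = 30L,
                               gc_target = 0.55, feature_plan = list()))
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force heme-motif oracle: position-by-position window check with
# the shortest-match-first, resume-after-H rule applied explicitly
oracle_heme_count <- function(seq, mode = c("canonical", "literal")) {
  mode <- match.arg(mode)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  count <- 0L
  i <- 1L
  while (i <= n) {
    w5 <- i + 4L <= n && ch[i] == "C" && ch[i + 3L] == "C" && ch[i + 4L] == "H"
    w6 <- i + 5L <= n && ch[i] == "C" && ch[i + 4L] == "C" && ch[i + 5L] == "H"
    l4 <- i + 3L <= n && ch[i] == "C" && ch[i + 3L] == "H"
    l5 <- i + 4L <= n && ch[i] == "C" && ch[i + 4L] == "H"
    hit <- if (mode == "canonical") {
      if (w5) 5L else if (w6) 6L else 0L
    } else {
      if (l4) 4L else if (l5) 5L else 0L
    }
    if (hit > 0L) {
      count <- count + 1L
      i <- i + hit
    } else i <- i + 1L
  }
  count
}

# independent union-find for connected-component oracles
uf_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_along(edges_a)) {
    ra <- find(match(edges_a[k], nodes))
    rb <- find(match(edges_b[k], nodes))
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, roots)
}

empty_features_df <- function() {
  data.frame(feature_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             kind = character(), product = character(),
             locus_tag = character(), partial = logical(),
             stringsAsFactors = FALSE)
}

make_features <- function(n_cds, products, replicon = "chr", start0 = 0L,
                          gene_len = 90L, gap = 50L, strand = "+") {
  starts <- start0 + (seq_len(n_cds) - 1L) * (gene_len + gap)
  data.frame(feature_id = sprintf("g%04d", seq_len(n_cds)),
             replicon_id = replicon, start = starts, end = starts + gene_len,
             strand = rep(strand, length.out = n_cds), kind = "CDS",
             product = rep(products, length.out = n_cds),
             locus_tag = sprintf("g%04d", seq_len(n_cds)), partial = FALSE,
             stringsAsFactors = FALSE)
}
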