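# Shared fixture builders; everything is generated in code.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small expression file: 3 features x 3 samples, one all-zero row.
expression_lines <- function() {
  c("feature\ts1\ts2\ts3",
    "gA\t1.5\t2.0\t3.0",
    "gZero\t0\t0\t0",
    "gB\t-1.0\t0.5\t2.5")
}

# Random directed pathway edge table over `n_genes` genes.
random_pathway_table <- function(n_pathways, n_genes, edges_per_pathway = 6) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  do.call(rbind, lapply(seq_len(n_pathways), function(p) {
    src <- sample(genes, edges_per_pathway, replace = TRUE)
    dst <- sample(genes, edges_per_pathway, replace = TRUE)
    keep <- src != dst
    data.frame(source = src[keep], target = dst[keep],
               type = sample(c("activate", "inhibit"), sum(keep), TRUE),
               pathway = sprintf("pw%02d", p), stringsAsFactors = FALSE)
  }))
}

# Random GDPN (with virtual node) over a connected-ish random edge set.
random_gdpn <- function(n_nodes, n_edges) {
  genes <- sprintf("g%03d", seq_len(n_nodes))
  src <- sample(genes, n_edges, replace = TRUE)
  dst <- sample(genes, n_edges, replace = TRUE)
  keep <- src != dst
  edges <- data.frame(source = src[keep], target = dst[keep],
                      type = "activate", pathway = "pw01",
                      stringsAsFactors = FALSE)
  build_gdpn(edges)
}

# Fabricated diff_stats with given t and p values.
make_stats <- function(ids, t, p = rep(0.01, length(ids))) {
  res <- data.frame(feature = ids, t = t, p = p,
                    sign = ifelse(t < 0, -1L, 1L),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  rownames(res) <- ids
  class(res) <- c("diff_stats", "data.frame")
  res
}

# Tiny planted bundle that runs the whole pipeline quickly.
small_bundle <- function(seed = 5L, ...) {
  generate_dataset(synthetic_config(
    n_genes = 120L, n_mirnas = 30L, n_normal = 24L, n_cancer = 24L,
    n_signal_mirnas = 5L, seed = seed, ...))
}

# O(n^2) pair-enumeration AUC with the ties-count-half convention.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == "cancer"]
  neg <- scores[labels == "normal"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}
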