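#' Configuration for the synthetic bundle generator
#'
#' Defaults describe a two-group study of moderate size with a clearly
#' planted regulatory signal: 500 genes and 100 miRNAs measured on 60
#' normal and 60 cancer samples, 10 signal miRNAs shifted by 1.5
#' within-group standard deviations between groups, each repressing a
#' private set of target genes shifted by the same amount in the opposite
#' direction, against unit Gaussian noise on a scale-free-like directed
#' pathway graph.
#'
#' @param n_genes,n_mirnas Feature counts.
#' @param n_normal,n_cancer Samples per group.
#' @param n_signal_mirnas Number of miRNAs with a planted group effect.
#' @param targets_per_mirna Targets sampled per miRNA.
#' @param gene_effect_size,mirna_effect_size Planted group-mean shifts, in
#'   units of `noise_sd`.
#' @param noise_sd Within-group standard deviation.
#' @param edges_per_node Preferential-attachment edges added per new node.
#' @param n_pathways Number of pathway ids the graph edges are spread over.
#' @param seed Integer seed; the bundle is fully determined by it (together
#'   with `structure_seed`).
#' @param structure_seed Seed for the regulatory structure (pathway graph,
#'   target map, signal miRNA identities and directions). Defaults to
#'   `seed`. Two bundles generated with the same `structure_seed` but
#'   different `seed`s share their biology and differ only in sampling —
#'   the situation two cohorts of the same disease are in, and the setting
#'   cross-dataset validation assumes.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500L, n_mirnas = 100L,
                             n_normal = 60L, n_cancer = 60L,
                             n_signal_mirnas = 10L,
                             targets_per_mirna = 3L,
                             gene_effect_size = 1.5,
                             mirna_effect_size = 1.5,
                             noise_sd = 1.0, edges_per_node = 2L,
                             n_pathways = 10L, seed = 1L,
                             structure_seed = seed) {
  cfg <- list(n_genes = n_genes, n_mirnas = n_mirnas, n_normal = n_normal,
              n_cancer = n_cancer, n_signal_mirnas = n_signal_mirnas,
              targets_per_mirna = targets_per_mirna,
              gene_effect_size = gene_effect_size,
              mirna_effect_size = mirna_effect_size, noise_sd = noise_sd,
              edges_per_node = edges_per_node, n_pathways = n_pathways,
              seed = seed, structure_seed = structure_seed)
  counts <- c(n_genes, n_mirnas, n_normal, n_cancer, n_signal_mirnas,
              targets_per_mirna, edges_per_node, n_pathways)
  if (any(counts < 1)) stop("all counts must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_signal_mirnas > n_mirnas) {
    stop("n_signal_mirnas exceeds n_mirnas")
  }
  if (targets_per_mirna > n_genes) {
    stop("targets_per_mirna exceeds n_genes")
  }
  if (n_signal_mirnas * targets_per_mirna > n_genes) {
    stop("not enough genes for disjoint planted target sets")
  }
  if (gene_effect_size < 0 || mirna_effect_size < 0) {
    stop("effect sizes must be nonnegative")
  }
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

#' Generate a fully self-contained synthetic bundle
#'
#' Emulates the data structure the pipeline assumes, without downloads:
#'
#' * a directed pathway graph grown by preferential attachment (heavy-tailed
#'   degrees) with random edge orientation, edges spread over
#'   `n_pathways` pathway ids with random interaction types;
#' * a many-to-many miRNA-target map sampled uniformly;
#' * two-group Gaussian expression on the z scale: baseline
#'   `N(0, noise_sd)`, with each signal miRNA shifted in cancer by
#'   `mirna_effect_size` in a random direction and each of its planted
#'   targets shifted by `gene_effect_size` in the opposite direction.
#'
#' Planted target sets of distinct signal miRNAs are disjoint so planted
#' effects never conflict, and every planted target is a pathway-graph
#' member gene so it survives the network filter.
#'
#' @param config A [synthetic_config()].
#' @return Bundle list: `gene_expr`, `mir_expr`, `phen`, `pathways`,
#'   `pairs`, and `truth` (signal miRNA ids, per-miRNA direction and planted
#'   target genes with directions).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  set.seed(config$structure_seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mirs <- sprintf("mir%03d", seq_len(config$n_mirnas))
  samples <- c(sprintf("N%03d", seq_len(config$n_normal)),
               sprintf("C%03d", seq_len(config$n_cancer)))
  phen <- stats::setNames(rep(c("normal", "cancer"),
                              c(config$n_normal, config$n_cancer)), samples)

  # scale-free-like directed graph: preferential attachment, then each
  # edge's direction flipped with probability 1/2
  pa <- igraph::sample_pa(config$n_genes, m = config$edges_per_node,
                          directed = TRUE)
  el <- igraph::as_edgelist(pa)
  flip <- stats::runif(nrow(el)) < 0.5
  el[flip, ] <- el[flip, c(2L, 1L)]
  pathways <- data.frame(
    source = genes[el[, 1L]],
    target = genes[el[, 2L]],
    type = sample(c("activate", "inhibit", "other"), nrow(el),
                  replace = TRUE, prob = c(0.45, 0.45, 0.1)),
    pathway = sample(sprintf("pw%02d", seq_len(config$n_pathways)),
                     nrow(el), replace = TRUE),
    stringsAsFactors = FALSE)
  pathways <- validate_pathway_table(pathways)
  member_genes <- sort(unique(c(pathways$source, pathways$target)))

  # disjoint planted target sets for signal miRNAs, drawn from graph members
  signal_mirs <- mirs[seq_len(config$n_signal_mirnas)]
  pool <- sample(member_genes)
  pairs_list <- list()
  truth_targets <- list()
  direction <- stats::setNames(sample(c(1, -1), config$n_signal_mirnas,
                                      replace = TRUE), signal_mirs)
  used <- 0L
  for (mir in signal_mirs) {
    tg <- pool[(used + 1L):(used + config$targets_per_mirna)]
    used <- used + config$targets_per_mirna
    pairs_list[[mir]] <- data.frame(mirna = mir, gene = tg,
                                    stringsAsFactors = FALSE)
    truth_targets[[mir]] <- tg
  }
  for (mir in setdiff(mirs, signal_mirs)) {
    tg <- sample(genes, config$targets_per_mirna)
    pairs_list[[mir]] <- data.frame(mirna = mir, gene = tg,
                                    stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs_list)
  rownames(pairs) <- NULL

  # sampling phase: offset keeps the expression stream distinct from the
  # structure stream even when structure_seed == seed
  set.seed(config$seed + 499979L)
  n_samp <- length(samples)
  is_cancer <- phen == "cancer"
  gene_expr <- matrix(stats::rnorm(config$n_genes * n_samp,
                                   sd = config$noise_sd),
                      nrow = config$n_genes,
                      dimnames = list(genes, samples))
  mir_expr <- matrix(stats::rnorm(config$n_mirnas * n_samp,
                                  sd = config$noise_sd),
                     nrow = config$n_mirnas,
                     dimnames = list(mirs, samples))
  gene_direction <- stats::setNames(numeric(0), character(0))
  for (mir in signal_mirs) {
    d <- direction[[mir]]
    mir_expr[mir, is_cancer] <- mir_expr[mir, is_cancer] +
      d * config$mirna_effect_size * config$noise_sd
    tg <- truth_targets[[mir]]
    gene_expr[tg, is_cancer] <- gene_expr[tg, is_cancer] -
      d * config$gene_effect_size * config$noise_sd
    gene_direction[tg] <- -d
  }

  list(
    gene_expr = new_expression_matrix(gene_expr, "gene"),
    mir_expr = new_expression_matrix(mir_expr, "miRNA"),
    phen = phen,
    pathways = pathways,
    pairs = pairs,
    truth = list(signal_mirnas = signal_mirs,
                 mirna_direction = direction,
                 targets = truth_targets,
                 gene_direction = gene_direction,
                 config = config)
  )
}

#' Fixed hand-checkable micro fixture
#'
#' A deterministic toy bundle (6 genes, 2 miRNAs, 4 + 4 samples, one
#' pathway) small enough that every stage — t-scores, walk weights, the
#' activity formula — can be verified against a direct calculation.
#' `mir001` is the planted signal miRNA: up in cancer, with down-shifted
#' targets `g1`-`g3`; `mir002` is null.
#'
#' @return Bundle list in the same shape as [generate_dataset()].
#' @export
worked_toy <- function() {
  samples <- c("N1", "N2", "N3", "N4", "C1", "C2", "C3", "C4")
  phen <- stats::setNames(rep(c("normal", "cancer"), each = 4L), samples)
  # small fixed within-group jitter keeps every variance positive
  jit <- c(0.2, -0.1, 0.1, -0.2)
  base <- rbind(
    g1 = c(jit, jit - 2),        # planted down in cancer
    g2 = c(jit, jit - 2.5),      # planted down in cancer
    g3 = c(jit, jit - 1.8),      # planted down in cancer
    g4 = c(jit, jit + 0.1),      # null
    g5 = c(jit, jit - 0.05),     # null
    g6 = c(rev(jit), jit)        # null
  )
  colnames(base) <- samples
  mirs <- rbind(
    mir001 = c(jit, jit + 2.2),  # planted up in cancer
    mir002 = c(rev(jit), jit + 0.05)
  )
  colnames(mirs) <- samples
  pathways <- data.frame(
    source = c("g1", "g1", "g2", "g3", "g5"),
    target = c("g2", "g3", "g4", "g4", "g6"),
    type = c("activate", "inhibit", "activate", "activate", "other"),
    pathway = "toy",
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    mirna = c("mir001", "mir001", "mir001", "mir002"),
    gene = c("g1", "g2", "g3", "g5"),
    stringsAsFactors = FALSE)
  list(
    gene_expr = new_expression_matrix(base, "gene"),
    mir_expr = new_expression_matrix(mirs, "miRNA"),
    phen = phen,
    pathways = pathways,
    pairs = pairs,
    truth = list(signal_mirnas = "mir001",
                 mirna_direction = c(mir001 = 1),
                 targets = list(mir001 = c("g1", "g2", "g3")),
                 gene_direction = c(g1 = -1, g2 = -1, g3 = -1))
  )
}
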