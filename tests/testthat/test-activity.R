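toy_graph <- function(genes) {
  n <- length(genes)
  build_gdpn(data.frame(source = genes[-n], target = genes[-1],
                        type = "activate", pathway = "p1",
                        stringsAsFactors = FALSE))
}

test_that("the inverse-regulation filter applies all three predicates", {
  g <- toy_graph(c("gA", "gB", "gC"))
  w <- setNames(c(0.4, 0.3, 0.2, 0.1), c("gA", "gB", "gC", VIRTUAL_NODE))
  mir_stats <- make_stats(c("m1", "m2"), t = c(3, 2), p = c(0.01, 0.5))
  gene_stats <- make_stats(c("gA", "gB", "gC", "gD"),
                           t = c(-2, 2, -3, -4),
                           p = c(0.03, 0.01, 0.2, 0.01))
  pairs <- data.frame(
    mirna = c("m1", "m1", "m1", "m1", "m2"),
    gene = c("gA", "gB", "gC", "gD", "gA"),
    stringsAsFactors = FALSE)
  defs <- select_sde_targets(mir_stats, gene_stats, pairs, g, w)
  # m2 fails the miRNA p filter entirely
  expect_equal(names(defs), "m1")
  # gA: discordant + significant + in graph -> kept
  # gB: concordant sign -> out; gC: p too big -> out; gD: not in graph -> out
  expect_equal(defs$m1$genes, "gA")
  expect_equal(unname(defs$m1$weights), 0.4)
  expect_equal(unname(defs$m1$signs), -1L)
})

test_that("filtering equals exhaustive predicate enumeration on random stats", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:30)
  g <- toy_graph(genes[1:20])   # genes 21..30 are outside the network
  w <- setNames(runif(21), c(genes[1:20], VIRTUAL_NODE))
  mirs <- sprintf("m%02d", 1:10)
  mir_stats <- make_stats(mirs, t = rnorm(10), p = runif(10, 0, 0.2))
  gene_stats <- make_stats(genes, t = rnorm(30), p = runif(30, 0, 0.2))
  pairs <- expand.grid(mirna = mirs, gene = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 150), ]
  defs <- select_sde_targets(mir_stats, gene_stats, pairs, g, w)
  # brute force: loop every pair, apply the three predicates literally
  expected <- list()
  for (i in seq_len(nrow(pairs))) {
    mir <- pairs$mirna[i]; gene <- pairs$gene[i]
    if (mir_stats[mir, "p"] >= 0.05) next
    if (gene_stats[gene, "p"] >= 0.05) next
    if (mir_stats[mir, "t"] * gene_stats[gene, "t"] >= 0) next
    if (!gene %in% gdpn_genes(g)) next
    expected[[mir]] <- sort(unique(c(expected[[mir]], gene)))
  }
  expect_setequal(names(defs), names(expected))
  for (mir in names(expected)) {
    expect_equal(defs[[mir]]$genes, expected[[mir]])
  }
})

test_that("single-gene subpathways reduce to the signed z row exactly", {
  set.seed(32)
  z <- matrix(rnorm(8), nrow = 1, dimnames = list("gA", paste0("s", 1:8)))
  def <- list(mirna = "m1", genes = "gA",
              weights = c(gA = 0.37), signs = c(gA = -1L), n = 1L)
  expect_equal(activity_value(def, z), -z[1, ], ignore_attr = TRUE,
               tolerance = 1e-15)
})

test_that("two-gene activity matches the hand-evaluated weighted form", {
  set.seed(33)
  z <- matrix(rnorm(12), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  def <- list(mirna = "m1", genes = c("g1", "g2"),
              weights = c(g1 = 3, g2 = 4),
              signs = c(g1 = 1L, g2 = -1L), n = 2L)
  expect_equal(activity_value(def, z),
               (3 * z[1, ] - 4 * z[2, ]) / 5, ignore_attr = TRUE,
               tolerance = 1e-12)
  # the no-radical variant divides by 25 instead of 5
  expect_equal(activity_value(def, z, denominator = "sum_sq"),
               (3 * z[1, ] - 4 * z[2, ]) / 25, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("activity rows match a brute-force loop on random definitions", {
  set.seed(34)
  genes <- sprintf("g%03d", 1:40)
  z <- matrix(rnorm(40 * 12), nrow = 40,
              dimnames = list(genes, paste0("s", 1:12)))
  for (i in 1:50) {
    k <- sample(1:6, 1)
    gs <- sample(genes, k)
    def <- list(mirna = "m", genes = gs,
                weights = setNames(runif(k), gs),
                signs = setNames(sample(c(-1L, 1L), k, TRUE), gs), n = k)
    a <- activity_value(def, z)
    oracle <- numeric(12)
    for (s in 1:12) {
      num <- 0
      for (gene in gs) {
        num <- num + def$weights[[gene]] * def$signs[[gene]] * z[gene, s]
      }
      oracle[s] <- num / sqrt(sum(def$weights^2))
    }
    expect_equal(unname(a), oracle, tolerance = 1e-12)
  }
})

test_that("activity is invariant to positive rescaling of the weights", {
  set.seed(35)
  z <- matrix(rnorm(30), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  def <- list(mirna = "m1", genes = c("g1", "g2", "g3"),
              weights = setNames(c(0.2, 0.5, 0.3), c("g1", "g2", "g3")),
              signs = setNames(c(1L, -1L, 1L), c("g1", "g2", "g3")), n = 3L)
  def_scaled <- def
  def_scaled$weights <- def$weights * 137
  expect_equal(activity_value(def, z), activity_value(def_scaled, z),
               tolerance = 1e-12)
})

test_that("activity rows sum to zero over samples when z rows are centred", {
  set.seed(36)
  x <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  z <- zscore_rows(x)
  def <- list(mirna = "m1", genes = rownames(z),
              weights = setNames(runif(4), rownames(z)),
              signs = setNames(c(1L, 1L, -1L, -1L), rownames(z)), n = 4L)
  expect_equal(sum(activity_value(def, z)), 0, tolerance = 1e-10)
})

test_that("profiles stack rows deterministically and permute with samples", {
  set.seed(37)
  genes <- paste0("g", 1:6)
  z <- matrix(rnorm(60), nrow = 6, dimnames = list(genes, paste0("s", 1:10)))
  defs <- list(
    m2 = list(mirna = "m2", genes = genes[1:3],
              weights = setNames(runif(3), genes[1:3]),
              signs = setNames(c(1L, -1L, 1L), genes[1:3]), n = 3L),
    m1 = list(mirna = "m1", genes = genes[4:5],
              weights = setNames(runif(2), genes[4:5]),
              signs = setNames(c(-1L, 1L), genes[4:5]), n = 2L),
    m3 = list(mirna = "m3", genes = genes[6],
              weights = setNames(0.5, genes[6]),
              signs = setNames(1L, genes[6]), n = 1L))
  prof <- infer_activity_profile(defs, z)
  expect_equal(dim(prof), c(3L, 10L))
  expect_equal(rownames(prof), c("m2", "m1", "m3"))  # by descending n
  perm <- sample(10)
  prof_perm <- infer_activity_profile(defs, z[, perm])
  attr(prof_perm, "definitions") <- NULL
  expect_equal(unname(prof_perm), unname(prof[, perm]), tolerance = 1e-12)
  for (mir in rownames(prof)) {
    expect_equal(prof[mir, ], activity_value(defs[[mir]], z),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("flipping phenotype labels flips every activity row's sign", {
  bundle <- small_bundle(seed = 38)
  g <- build_gdpn(bundle$pathways)
  m <- build_transition(g)
  z <- zscore_rows(bundle$gene_expr)
  run <- function(phen) {
    gene_stats <- ttest_two_group(bundle$gene_expr, phen)
    mir_stats <- ttest_two_group(bundle$mir_expr, phen)
    w <- drw_walk(m, initial_weights(gene_stats, g))
    defs <- select_sde_targets(mir_stats, gene_stats, bundle$pairs, g, w)
    infer_activity_profile(defs, z)
  }
  prof <- run(bundle$phen)
  flipped <- setNames(ifelse(bundle$phen == "normal", "cancer", "normal"),
                      names(bundle$phen))
  prof_flip <- run(flipped)
  shared <- intersect(rownames(prof), rownames(prof_flip))
  expect_gt(length(shared), 0)
  expect_equal(prof_flip[shared, , drop = FALSE],
               -prof[shared, , drop = FALSE], tolerance = 1e-9)
})
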