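test_that("AUC follows the rank statistic with ties counted half", {
  labels <- c(rep("normal", 4), rep("cancer", 4))
  perfect <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(compute_metrics(perfect, labels)$auc, 1.0)
  expect_equal(compute_metrics(rep(0, 8), labels)$auc, 0.5)
  set.seed(51)
  scores <- c(0.1, 0.4, 0.4, 0.2, 0.9, 0.4, 0.8, 0.3)  # one tie across groups
  met <- compute_metrics(scores, labels)
  expect_equal(met$auc, auc_pair_oracle(scores, labels))
  expect_error(compute_metrics(1:4, rep("cancer", 4)), "single class")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  labels <- sample(c("normal", "cancer"), 60, replace = TRUE)
  scores <- rnorm(60) + (labels == "cancer")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("normal", "cancer"),
    direction = "<", quiet = TRUE)))
  expect_equal(compute_metrics(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("accuracy uses hard predictions and reports class-wise rates", {
  labels <- c("normal", "normal", "cancer", "cancer")
  met <- compute_metrics(c(-1, 1, -1, 1), labels,
                         predicted = c("normal", "cancer", "normal",
                                       "cancer"))
  expect_equal(met$accuracy, 0.5)
  expect_equal(met$sensitivity, 0.5)
  expect_equal(met$specificity, 0.5)
})

test_that("stratified folds preserve class proportions within one sample", {
  set.seed(53)
  labels <- rep(c("normal", "cancer"), c(12, 48))
  for (i in 1:20) {
    fold <- mirsubpath:::stratified_folds(labels, 5)
    for (f in 1:5) {
      tab <- table(labels[fold == f])
      expect_true(abs(tab[["normal"]] - 12 / 5) < 1)
      expect_true(abs(tab[["cancer"]] - 48 / 5) < 1)
    }
  }
})

test_that("one repetition yields 15 within-dataset classifier instances", {
  bundle <- small_bundle(seed = 54)
  rpt <- within_dataset_cv(bundle$gene_expr, bundle$mir_expr, bundle$phen,
                           bundle$pairs, bundle$pathways, reps = 1,
                           seed = 3)
  expect_equal(rpt$n_instances, 15L)
  expect_equal(nrow(rpt$instances), 15L)
  expect_equal(length(unique(rpt$instances$classifier)), 3L)
  expect_true(all(rpt$instances$auc >= 0 & rpt$instances$auc <= 1))
  expect_true(all(rpt$instances$accuracy >= 0 &
                    rpt$instances$accuracy <= 1))
  expect_equal(sum(rpt$instances$held_out), 3L)
})

test_that("within-dataset reports are reproducible from the seed", {
  bundle <- small_bundle(seed = 55)
  run <- function() {
    within_dataset_cv(bundle$gene_expr, bundle$mir_expr, bundle$phen,
                      bundle$pairs, bundle$pathways, reps = 1, seed = 11)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$instances$auc, r2$instances$auc)
  expect_identical(r1$frequency, r2$frequency)
  expect_identical(r1$risk_biomarkers, r2$risk_biomarkers)
})

test_that("one cross-dataset repetition yields 5 instances", {
  b1 <- small_bundle(seed = 56, structure_seed = 560)
  b2 <- small_bundle(seed = 57, structure_seed = 560)
  rpt <- cross_dataset_cv(b1, b2, reps = 1, seed = 4)
  expect_equal(rpt$n_instances, 5L)
  expect_true(all(rpt$instances$auc >= 0 & rpt$instances$auc <= 1))
})

test_that("cross-dataset transfer approaches within-dataset performance", {
  b1 <- small_bundle(seed = 58, structure_seed = 580)
  b2 <- small_bundle(seed = 59, structure_seed = 580)
  within_rpt <- within_dataset_cv(b1$gene_expr, b1$mir_expr, b1$phen,
                                  b1$pairs, b1$pathways, reps = 1, seed = 5)
  cross_rpt <- cross_dataset_cv(b1, b2, reps = 1, seed = 5)
  expect_lt(abs(cross_rpt$mean_auc - within_rpt$mean_auc), 0.1)
})

test_that("baseline summaries match their direct oracles", {
  set.seed(60)
  genes <- paste0("g", 1:5)
  z <- matrix(rnorm(50), nrow = 5, dimnames = list(genes, paste0("s", 1:10)))
  defs <- list(mX = list(mirna = "mX", genes = genes,
                         weights = setNames(runif(5), genes),
                         signs = setNames(rep(1L, 5), genes), n = 5L))
  expect_equal(unname(baseline_activity("mean", defs, z)[1, ]),
               unname(colMeans(z)), tolerance = 1e-12)
  expect_equal(unname(baseline_activity("median", defs, z)[1, ]),
               unname(apply(z, 2, median)), tolerance = 1e-12)
  # rank-1 case: PCA score of two identical rows is proportional to them
  z2 <- z[c(1, 1), ]
  rownames(z2) <- c("g1", "g2")
  defs2 <- list(mY = list(mirna = "mY", genes = c("g1", "g2"),
                          weights = c(g1 = 1, g2 = 1),
                          signs = c(g1 = 1L, g2 = 1L), n = 2L))
  pc <- baseline_activity("pca", defs2, z2)[1, ]
  expect_equal(abs(cor(pc, z2[1, ])), 1, tolerance = 1e-9)
  expect_gt(cor(pc, colMeans(z2)), 0)  # sign anchored to the member mean
  # single-gene subpathway: mean = median = the z row itself
  defs1 <- list(mZ = list(mirna = "mZ", genes = "g1",
                          weights = c(g1 = 1), signs = c(g1 = 1L), n = 1L))
  expect_equal(unname(baseline_activity("mean", defs1, z)[1, ]),
               unname(z[1, ]))
  expect_equal(unname(baseline_activity("median", defs1, z)[1, ]),
               unname(z[1, ]))
  # gene/mirna schemes pass the z matrices through
  expect_identical(baseline_activity("gene", z_genes = z), z)
})

test_that("deleted-pair counts follow round(fraction x total) exactly", {
  bundle <- small_bundle(seed = 61)
  n <- nrow(bundle$pairs)
  for (frac in c(0, 0.1, 0.25, 0.5)) {
    set.seed(8)
    out <- mirsubpath:::delete_target_pairs(bundle$pairs, frac)
    expect_equal(nrow(out), n - round(frac * n))
  }
})

test_that("zero deletion reproduces the unperturbed run exactly", {
  bundle <- small_bundle(seed = 62)
  tab <- edge_deletion_robustness(bundle, fractions = 0, reps = 2,
                                  seed = 7, cv_reps = 1)
  ref <- vapply(1:2, function(rep_i) {
    run_seed <- 7L + 1009L * rep_i
    within_dataset_cv(bundle$gene_expr, bundle$mir_expr, bundle$phen,
                      bundle$pairs, bundle$pathways, reps = 1,
                      seed = run_seed)$mean_auc
  }, numeric(1))
  expect_equal(tab$mean_auc, mean(ref), tolerance = 1e-12)
})

test_that("folds without surviving subpathways fall back to chance-level", {
  # zero effect sizes: the filters usually find nothing, which must surface
  # as uninformative classifiers rather than errors
  bundle <- generate_dataset(synthetic_config(
    n_genes = 120L, n_mirnas = 30L, n_normal = 20L, n_cancer = 20L,
    n_signal_mirnas = 5L, gene_effect_size = 0, mirna_effect_size = 0,
    seed = 63))
  rpt <- within_dataset_cv(bundle$gene_expr, bundle$mir_expr, bundle$phen,
                           bundle$pairs, bundle$pathways, reps = 1,
                           seed = 9)
  expect_equal(rpt$n_instances, 15L)
  empty <- rpt$instances$n_features == 0
  expect_true(all(rpt$instances$auc[empty] == 0.5))
})
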