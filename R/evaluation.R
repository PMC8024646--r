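#' AUC and accuracy of a scored two-group prediction
#'
#' AUC is the rank statistic of the decision values (probability that a
#' random cancer sample scores above a random normal sample, ties counted
#' half). Accuracy is the fraction of correct hard predictions at the
#' classifier's native threshold; when no hard predictions are supplied the
#' sign of the decision value is used. Class-wise rates are reported
#' alongside raw accuracy because imbalanced designs make raw accuracy alone
#' hard to read.
#'
#' @param decision_values Numeric scores, larger = more cancer-like.
#' @param labels Character labels (`"normal"`/`"cancer"`), same length.
#' @param predicted Optional character vector of hard predictions.
#' @return List with `auc`, `accuracy`, `sensitivity` (cancer recall) and
#'   `specificity` (normal recall).
#' @export
compute_metrics <- function(decision_values, labels, predicted = NULL) {
  is_cancer <- labels == "cancer"
  n1 <- sum(is_cancer)
  n0 <- sum(!is_cancer)
  if (n1 == 0L || n0 == 0L) stop("labels contain a single class")
  r <- rank(decision_values)
  auc <- (sum(r[is_cancer]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (is.null(predicted)) {
    predicted <- ifelse(decision_values > 0, "cancer", "normal")
  }
  list(
    auc = auc,
    accuracy = mean(predicted == labels),
    sensitivity = mean(predicted[is_cancer] == "cancer"),
    specificity = mean(predicted[!is_cancer] == "normal")
  )
}

# Stratified assignment of samples to k folds: per class, shuffle then deal
# round-robin, so class proportions differ by at most one sample per fold.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Folds where every part has both classes and at least `min_per_class`
# samples of each; resamples up to 10 times before giving up.
stratified_folds_checked <- function(labels, k, min_per_class = 1L) {
  for (attempt in 1:10) {
    fold <- stratified_folds(labels, k)
    ok <- all(vapply(seq_len(k), function(f) {
      tab <- table(factor(labels[fold == f], levels = c("normal", "cancer")))
      all(tab >= min_per_class)
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not produce stratified folds with both classes in every part")
}

# Align the two expression matrices and the phenotype table on a shared
# sample order.
align_bundle_samples <- function(gene_expr, mir_expr, phen) {
  shared <- intersect(colnames(gene_expr), colnames(mir_expr))
  shared <- shared[shared %in% names(phen)]
  if (length(shared) < 4L) {
    stop("fewer than 4 samples shared between gene and miRNA matrices")
  }
  list(gene_expr = gene_expr[, shared, drop = FALSE],
       mir_expr = mir_expr[, shared, drop = FALSE],
       phen = phen[shared])
}

restrict_defs <- function(defs, genes) {
  defs <- lapply(defs, function(d) {
    keep <- d$genes %in% genes
    if (!any(keep)) return(NULL)
    list(mirna = d$mirna, genes = d$genes[keep],
         weights = d$weights[d$genes[keep]],
         signs = d$signs[d$genes[keep]], n = sum(keep))
  })
  defs[!vapply(defs, is.null, logical(1))]
}

# Compute subpathway definitions and the feature profile for one choice of
# statistic samples. `stat_samples` are the sample ids whose labels feed the
# t-tests (and hence the walk seeds and Eq-sign structure); the profile is
# returned over all columns of `z_genes`.
build_feature_profile <- function(method, stat_samples, gene_expr, mir_expr,
                                  phen, pairs, g, transition, z_genes,
                                  z_mirs, r, tol, K, alpha_gene, alpha_mir,
                                  denominator = "l2") {
  if (method == "gene") return(z_genes)
  if (method == "mirna") return(z_mirs)
  gene_stats <- ttest_two_group(gene_expr[, stat_samples, drop = FALSE], phen)
  mir_stats <- ttest_two_group(mir_expr[, stat_samples, drop = FALSE], phen)
  weights <- if (method == "drw") {
    p0 <- initial_weights(gene_stats, g)
    drw_walk(transition, p0, r = r, tol = tol)
  } else {
    stats::setNames(rep(1, length(igraph::V(g))), igraph::V(g)$name)
  }
  defs <- select_sde_targets(mir_stats, gene_stats, pairs, g, weights,
                             alpha_gene = alpha_gene, alpha_mir = alpha_mir)
  defs <- restrict_defs(defs, rownames(z_genes))
  if (length(defs) == 0L) stop_no_subpathways()
  if (method == "drw") {
    infer_activity_profile(defs, z_genes, denominator = denominator)
  } else {
    baseline_activity(method, defs, z_genes, z_mirs)
  }
}

# Raised when the differential/sign/network filters leave no subpathway;
# on signal-free data this is the expected outcome, not a defect, and the
# cross-validation folds translate it into an uninformative classifier.
stop_no_subpathways <- function() {
  stop(errorCondition("no miRNA-mediated subpathway survived the filters",
                      class = c("mirsubpath_no_subpathways", "error",
                                "condition")))
}

#' Within-dataset nested cross-validation
#'
#' One repetition splits the samples into five stratified parts; part five
#' is the held-out test set and parts one to four form the training set. The
#' training set is split into three stratified subparts; rotating which
#' subpart tunes yields three optimised classifiers (greedy AUC-driven SVM
#' forward selection over the top-`K` candidates ranked on the build
#' subpart). Each classifier is then scored on each of the five parts,
#' giving 15 classifier-by-test-part instances per repetition (150 for the
#' default `reps = 10`).
#'
#' In `strict` mode (default) the differential statistics, walk seeds and
#' subpathway definitions are recomputed from the build subpart only, and
#' the aggregate AUC/accuracy average only the instances whose test part is
#' the held-out fifth — an honest generalisation estimate. `pooled`
#' mode computes the statistics once on all samples and averages all
#' instances, including test parts overlapping the classifiers' own
#' training data; its aggregate is optimistic and reports flag it as leaky.
#'
#' @param gene_expr,mir_expr Gene / miRNA expression matrices
#'   (features x samples) with matched sample ids.
#' @param phen Named phenotype vector.
#' @param pairs miRNA-target pair table.
#' @param pathways Pathway edge table.
#' @param reps Number of repetitions (default 10).
#' @param seed Integer seed; every random choice derives from it.
#' @param K Candidate cap (default 50).
#' @param mode `"strict"` or `"pooled"`.
#' @param method Feature construction: `"drw"` (default), or the baselines
#'   `"mean"`, `"median"`, `"pca"`, `"gene"`, `"mirna"`.
#' @param r,tol Walk restart probability and convergence tolerance.
#' @param alpha_gene,alpha_mir Differential-expression thresholds.
#' @param risk_threshold Strict lower bound on selection frequency for risk
#'   biomarker calling; default one third of the instance count (50 when
#'   there are 150 instances).
#' @return An `evaluation_report` list: per-instance records, aggregate
#'   mean/sd AUC and accuracy, the feature frequency table, the called risk
#'   biomarkers, and all run parameters.
#' @export
within_dataset_cv <- function(gene_expr, mir_expr, phen, pairs, pathways,
                              reps = 10L, seed = 1L, K = 50L,
                              mode = c("strict", "pooled"),
                              method = c("drw", "mean", "median", "pca",
                                         "gene", "mirna"),
                              r = 0.7, tol = 1e-10,
                              alpha_gene = 0.05, alpha_mir = 0.05,
                              risk_threshold = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  al <- align_bundle_samples(gene_expr, mir_expr, phen)
  gene_expr <- al$gene_expr; mir_expr <- al$mir_expr; phen <- al$phen
  samples <- colnames(gene_expr)
  labels <- unname(phen[samples])

  g <- build_gdpn(pathways)
  transition <- if (method == "drw") build_transition(g) else NULL
  z_genes <- suppressWarnings(zscore_rows(gene_expr))
  z_mirs <- suppressWarnings(zscore_rows(mir_expr))

  profile_full <- NULL
  if (mode == "pooled" || method %in% c("gene", "mirna")) {
    profile_full <- build_feature_profile(
      method, samples, gene_expr, mir_expr, phen, pairs, g, transition,
      z_genes, z_mirs, r, tol, K, alpha_gene, alpha_mir)
  }

  set.seed(seed)
  records <- list()
  selected_sets <- list()
  for (rep_i in seq_len(reps)) {
    fold5 <- stratified_folds_checked(labels, 5L, min_per_class = 1L)
    test_part <- 5L
    train_idx <- which(fold5 != test_part)
    fold3 <- integer(length(labels))
    fold3[train_idx] <- stratified_folds_checked(labels[train_idx], 3L,
                                                 min_per_class = 2L)
    for (k in 1:3) {
      tune_idx <- which(fold3 == k)
      build_idx <- setdiff(train_idx, tune_idx)
      profile <- if (mode == "strict" && !method %in% c("gene", "mirna")) {
        tryCatch(
          build_feature_profile(
            method, samples[build_idx], gene_expr, mir_expr, phen, pairs,
            g, transition, z_genes, z_mirs, r, tol, K, alpha_gene,
            alpha_mir),
          mirsubpath_no_subpathways = function(cond) NULL)
      } else {
        profile_full
      }
      cls <- NULL
      if (!is.null(profile)) {
        ranking <- rank_candidates(profile[, build_idx, drop = FALSE],
                                   phen, K = K)
        cls <- greedy_forward_select(
          ranking,
          profile[ranking, build_idx, drop = FALSE],
          profile[ranking, tune_idx, drop = FALSE],
          phen, phen)
      }
      majority <- names(which.max(table(labels[build_idx])))
      for (f in 1:5) {
        eval_idx <- which(fold5 == f)
        if (is.null(cls)) {
          # no subpathway survived the filters on this build subset: the
          # fold contributes an uninformative classifier
          met <- list(auc = 0.5,
                      accuracy = mean(labels[eval_idx] == majority))
          feats <- character(0)
          nf <- 0L
          tune_auc <- NA_real_
        } else {
          sc <- svm_scores(cls$fit,
                           t(profile[ranking, eval_idx, drop = FALSE]))
          met <- compute_metrics(sc$decision, labels[eval_idx], sc$label)
          feats <- cls$features
          nf <- length(cls$features)
          tune_auc <- cls$tune_auc
        }
        records[[length(records) + 1L]] <- data.frame(
          rep = rep_i, classifier = k, test_part = f,
          held_out = f == test_part,
          auc = met$auc, accuracy = met$accuracy,
          n_features = nf,
          tune_auc = tune_auc,
          stringsAsFactors = FALSE)
        selected_sets[[length(selected_sets) + 1L]] <- feats
      }
    }
  }
  finalize_report("within", records, selected_sets, mode, method, seed,
                  reps, K, r, risk_threshold)
}

finalize_report <- function(scheme, records, selected_sets, mode, method,
                            seed, reps, K, r, risk_threshold) {
  inst <- do.call(rbind, records)
  inst$features <- I(selected_sets)
  agg_idx <- if (scheme == "within" && mode == "strict") {
    which(inst$held_out)
  } else {
    seq_len(nrow(inst))
  }
  freq <- feature_frequency(selected_sets)
  n_inst <- nrow(inst)
  if (is.null(risk_threshold)) risk_threshold <- floor(n_inst / 3)
  report <- list(
    scheme = scheme, mode = mode, method = method, seed = seed,
    reps = reps, K = K, r = r,
    leaky = (mode == "pooled"),
    n_instances = n_inst,
    instances = inst,
    mean_auc = mean(inst$auc[agg_idx]),
    sd_auc = stats::sd(inst$auc[agg_idx]),
    mean_accuracy = mean(inst$accuracy[agg_idx]),
    sd_accuracy = stats::sd(inst$accuracy[agg_idx]),
    frequency = freq,
    risk_threshold = risk_threshold,
    risk_biomarkers = call_risk_biomarkers(freq, risk_threshold)
  )
  class(report) <- c("evaluation_report", "list")
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s-dataset evaluation (%s mode, method=%s, seed=%d)\n",
              x$scheme, x$mode, x$method, x$seed))
  cat(sprintf("  %d classifier instances over %d repetition(s)\n",
              x$n_instances, x$reps))
  cat(sprintf("  mean AUC %.4f (sd %.4f), mean accuracy %.4f (sd %.4f)\n",
              x$mean_auc, x$sd_auc, x$mean_accuracy, x$sd_accuracy))
  cat(sprintf("  risk biomarkers (frequency > %d): %s\n", x$risk_threshold,
              if (length(x$risk_biomarkers)) {
                paste(x$risk_biomarkers, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Cross-dataset cross-validation
#'
#' Trains on one bundle and tests on an external bundle after intersecting
#' the gene and miRNA feature spaces. Each repetition splits the training
#' samples into five stratified parts; rotating which part tunes (the other
#' four build) yields five optimised classifiers, each scored on the entire
#' external test bundle — five instances per repetition, 50 for the default
#' `reps = 10`. Test-bundle activity uses the training-derived subpathway
#' definitions (weights and signs) with the test bundle's own z-scores.
#'
#' @param train_bundle,test_bundle Lists with `gene_expr`, `mir_expr`,
#'   `phen`, `pairs`, `pathways` (pairs/pathways are taken from the training
#'   bundle).
#' @inheritParams within_dataset_cv
#' @return An `evaluation_report` (scheme `"cross"`).
#' @export
cross_dataset_cv <- function(train_bundle, test_bundle, reps = 10L,
                             seed = 1L, K = 50L,
                             mode = c("strict", "pooled"),
                             r = 0.7, tol = 1e-10,
                             alpha_gene = 0.05, alpha_mir = 0.05,
                             risk_threshold = NULL) {
  mode <- match.arg(mode)
  shared_genes <- intersect(rownames(train_bundle$gene_expr),
                            rownames(test_bundle$gene_expr))
  shared_mirs <- intersect(rownames(train_bundle$mir_expr),
                           rownames(test_bundle$mir_expr))
  if (length(shared_genes) == 0L || length(shared_mirs) == 0L) {
    stop("empty gene or miRNA intersection between bundles")
  }
  tr <- align_bundle_samples(
    train_bundle$gene_expr[shared_genes, , drop = FALSE],
    train_bundle$mir_expr[shared_mirs, , drop = FALSE], train_bundle$phen)
  te <- align_bundle_samples(
    test_bundle$gene_expr[shared_genes, , drop = FALSE],
    test_bundle$mir_expr[shared_mirs, , drop = FALSE], test_bundle$phen)
  pairs <- train_bundle$pairs
  g <- build_gdpn(train_bundle$pathways)
  transition <- build_transition(g)
  z_tr <- suppressWarnings(zscore_rows(tr$gene_expr))
  z_te <- suppressWarnings(zscore_rows(te$gene_expr))
  z_mir_tr <- suppressWarnings(zscore_rows(tr$mir_expr))
  samples_tr <- colnames(tr$gene_expr)
  labels_tr <- unname(tr$phen[samples_tr])
  labels_te <- unname(te$phen[colnames(te$gene_expr)])

  compute_defs <- function(stat_samples) {
    gene_stats <- ttest_two_group(tr$gene_expr[, stat_samples, drop = FALSE],
                                  tr$phen)
    mir_stats <- ttest_two_group(tr$mir_expr[, stat_samples, drop = FALSE],
                                 tr$phen)
    p0 <- initial_weights(gene_stats, g)
    w <- drw_walk(transition, p0, r = r, tol = tol)
    defs <- select_sde_targets(mir_stats, gene_stats, pairs, g, w,
                               alpha_gene = alpha_gene,
                               alpha_mir = alpha_mir)
    restrict_defs(defs, intersect(rownames(z_tr), rownames(z_te)))
  }
  defs_full <- if (mode == "pooled") compute_defs(samples_tr)

  set.seed(seed)
  records <- list()
  selected_sets <- list()
  for (rep_i in seq_len(reps)) {
    fold5 <- stratified_folds_checked(labels_tr, 5L, min_per_class = 2L)
    for (k in 1:5) {
      tune_idx <- which(fold5 == k)
      build_idx <- which(fold5 != k)
      defs <- if (mode == "strict") {
        compute_defs(samples_tr[build_idx])
      } else {
        defs_full
      }
      if (length(defs) == 0L) {
        majority <- names(which.max(table(labels_tr[build_idx])))
        records[[length(records) + 1L]] <- data.frame(
          rep = rep_i, classifier = k, test_part = NA_integer_,
          held_out = TRUE, auc = 0.5,
          accuracy = mean(labels_te == majority),
          n_features = 0L, tune_auc = NA_real_,
          stringsAsFactors = FALSE)
        selected_sets[[length(selected_sets) + 1L]] <- character(0)
        next
      }
      prof_tr <- infer_activity_profile(defs, z_tr)
      prof_te <- infer_activity_profile(defs, z_te)
      ranking <- rank_candidates(prof_tr[, build_idx, drop = FALSE],
                                 tr$phen, K = K)
      ranking <- intersect(ranking, rownames(prof_te))
      cls <- greedy_forward_select(
        ranking,
        prof_tr[ranking, build_idx, drop = FALSE],
        prof_tr[ranking, tune_idx, drop = FALSE],
        tr$phen, tr$phen)
      sc <- svm_scores(cls$fit, t(prof_te[ranking, , drop = FALSE]))
      met <- compute_metrics(sc$decision, labels_te, sc$label)
      records[[length(records) + 1L]] <- data.frame(
        rep = rep_i, classifier = k, test_part = NA_integer_,
        held_out = TRUE, auc = met$auc, accuracy = met$accuracy,
        n_features = length(cls$features), tune_auc = cls$tune_auc,
        stringsAsFactors = FALSE)
      selected_sets[[length(selected_sets) + 1L]] <- cls$features
    }
  }
  finalize_report("cross", records, selected_sets, mode, "drw", seed, reps,
                  K, r, risk_threshold)
}

#' Baseline subpathway summaries
#'
#' Alternative feature constructions used for comparison against the
#' walk-weighted activity: per-subpathway mean or median of the member-gene
#' z rows, the first principal-component score of the member-gene z rows
#' (sign anchored to correlate positively with the member mean), or the raw
#' single-molecule z rows (`gene`, `mirna`).
#'
#' @param scheme One of `"mean"`, `"median"`, `"pca"`, `"gene"`, `"mirna"`.
#' @param defs Subpathway definitions (ignored for `gene`/`mirna`).
#' @param z_genes,z_mirs z-score matrices.
#' @return Feature-by-sample matrix.
#' @export
baseline_activity <- function(scheme = c("mean", "median", "pca", "gene",
                                         "mirna"),
                              defs = NULL, z_genes = NULL, z_mirs = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "gene") return(z_genes)
  if (scheme == "mirna") return(z_mirs)
  if (length(defs) == 0L) stop("no subpathway definitions supplied")
  rows <- lapply(defs, function(d) {
    genes <- intersect(d$genes, rownames(z_genes))
    if (length(genes) == 0L) return(NULL)
    zs <- z_genes[genes, , drop = FALSE]
    switch(scheme,
      mean = colMeans(zs),
      median = apply(zs, 2L, stats::median),
      pca = {
        if (nrow(zs) == 1L) {
          zs[1L, ]
        } else {
          score <- stats::prcomp(t(zs), center = TRUE, scale. = FALSE)$x[, 1L]
          if (stats::cor(score, colMeans(zs)) < 0) score <- -score
          score
        }
      })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("every subpathway was dropped")
  profile <- do.call(rbind, rows)
  dimnames(profile) <- list(names(rows), colnames(z_genes))
  profile
}

# Uniformly delete a share of target pairs; exact count round(frac * n).
delete_target_pairs <- function(pairs, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  n_del <- round(fraction * nrow(pairs))
  if (n_del == 0L) return(pairs)
  keep <- setdiff(seq_len(nrow(pairs)), sample.int(nrow(pairs), n_del))
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("deletion removed every miRNA-target pair")
  out
}

#' Edge-deletion robustness of the classification pipeline
#'
#' Measures how classification degrades as miRNA-target pairs are removed:
#' for each deletion fraction, the stated share of pairs is deleted
#' uniformly at random (re-sampled per repetition) and the full
#' within-dataset protocol is re-run on the reduced pair table. The
#' per-fraction mean AUC is expected to decrease as the deleted share grows.
#'
#' Seeds are derived so that fraction 0 reproduces the unperturbed run
#' exactly.
#'
#' @param bundle Input bundle (`gene_expr`, `mir_expr`, `phen`, `pairs`,
#'   `pathways`).
#' @param fractions Deletion fractions in `[0, 1)`; default
#'   `c(0, 0.1, 0.2, 0.3, 0.4, 0.5)`.
#' @param reps Deletion re-samples per fraction.
#' @param seed Integer seed.
#' @param cv_reps Repetitions inside each within-dataset run.
#' @param ... Passed to [within_dataset_cv()].
#' @return `data.frame` with columns `fraction`, `mean_auc`, `sd_auc`, `se`.
#' @export
edge_deletion_robustness <- function(bundle, fractions = seq(0, 0.5, 0.1),
                                     reps = 3L, seed = 1L, cv_reps = 1L,
                                     ...) {
  stopifnot(all(fractions >= 0), all(fractions < 1))
  out <- lapply(fractions, function(frac) {
    aucs <- vapply(seq_len(reps), function(rep_i) {
      run_seed <- seed + 1009L * rep_i
      set.seed(run_seed)
      pairs_del <- delete_target_pairs(bundle$pairs, frac)
      rpt <- within_dataset_cv(bundle$gene_expr, bundle$mir_expr,
                               bundle$phen, pairs_del, bundle$pathways,
                               reps = cv_reps, seed = run_seed, ...)
      rpt$mean_auc
    }, numeric(1))
    data.frame(fraction = frac, mean_auc = mean(aucs),
               sd_auc = stats::sd(aucs),
               se = stats::sd(aucs) / sqrt(length(aucs)))
  })
  do.call(rbind, out)
}
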