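#' Rank candidate subpathways by differential activity
#'
#' Scores every activity row with a two-group t-test and returns the
#' identifiers of the `K` most significant subpathways, ordered by ascending
#' p-value (ties broken lexicographically by id so the ranking is
#' deterministic).
#'
#' @param profile Activity matrix (subpathways x samples).
#' @param phen Named phenotype vector covering the profile's samples.
#' @param K Cap on the number of candidates (default 50).
#' @return Character vector of subpathway ids, best first.
#' @export
rank_candidates <- function(profile, phen, K = 50L) {
  if (nrow(profile) < 1L) stop("activity profile has no rows")
  st <- ttest_two_group(profile, phen)
  st <- st[!st$degenerate & !is.na(st$p), , drop = FALSE]
  if (nrow(st) == 0L) stop("no testable activity rows")
  ord <- order(st$p, st$feature)
  utils::head(st$feature[ord], K)
}

# Fit a radial-kernel SVM on samples x features, z-standardising each
# feature with training-fold statistics only. Library defaults elsewhere
# (cost 1, gamma 1/#features).
fit_svm <- function(x_train, y_train) {
  center <- colMeans(x_train)
  scale_ <- apply(x_train, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x_train, center = center, scale = scale_)
  model <- e1071::svm(xs, y_train, kernel = "radial", scale = FALSE)
  list(model = model, center = center, scale = scale_,
       features = colnames(x_train))
}

# Decision values oriented so that larger means more cancer-like, plus hard
# label predictions.
svm_scores <- function(fit, x_new) {
  xs <- scale(x_new[, fit$features, drop = FALSE],
              center = fit$center, scale = fit$scale)
  pred <- stats::predict(fit$model, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 names the column "A/B" with positive values favouring class A
  if (startsWith(colnames(dv)[1L], "normal")) dv <- -dv
  list(decision = as.vector(dv), label = as.character(pred))
}

#' Greedy AUC-driven forward feature selection with an SVM
#'
#' Builds the first classifier from the top-ranked candidate alone, then
#' walks down the ranking once: each candidate is tentatively added, the SVM
#' is refit on the training samples, and the candidate is kept only if the
#' AUC on the disjoint tuning samples strictly increases. Strict improvement
#' prevents unbounded feature accretion on AUC plateaus (an exact duplicate
#' of an already-selected feature can never be added).
#'
#' @param ranking Candidate ids from [rank_candidates()].
#' @param train_profile,tune_profile Activity matrices
#'   (subpathways x samples) for the disjoint training and tuning samples.
#' @param train_labels,tune_labels Phenotype vectors named by sample.
#' @return List with `features` (selected ids), `fit` (the final SVM fit),
#'   `tune_auc` and `auc_path` (tuning AUC after each accepted feature).
#' @export
greedy_forward_select <- function(ranking, train_profile, tune_profile,
                                  train_labels, tune_labels) {
  stopifnot(length(ranking) >= 1L)
  if (length(unique(tune_labels)) < 2L) {
    stop("tuning set lacks one of the classes")
  }
  y_train <- factor(train_labels[colnames(train_profile)],
                    levels = c("normal", "cancer"))
  y_tune <- tune_labels[colnames(tune_profile)]
  xtr <- t(train_profile)
  xtu <- t(tune_profile)

  score_set <- function(features) {
    fit <- fit_svm(xtr[, features, drop = FALSE], y_train)
    sc <- svm_scores(fit, xtu)
    list(fit = fit, auc = compute_metrics(sc$decision, y_tune)$auc)
  }

  selected <- ranking[1L]
  current <- score_set(selected)
  auc_path <- current$auc
  for (cand in ranking[-1L]) {
    trial <- score_set(c(selected, cand))
    if (trial$auc > current$auc) {
      selected <- c(selected, cand)
      current <- trial
      auc_path <- c(auc_path, trial$auc)
    }
  }
  list(features = selected, fit = current$fit, tune_auc = current$auc,
       auc_path = auc_path)
}

#' Tabulate feature frequencies across classifier instances
#'
#' @param selected_sets List of character vectors, one per classifier
#'   instance, each the instance's selected feature set.
#' @return Named integer vector of counts with attribute `n_instances`.
#' @export
feature_frequency <- function(selected_sets) {
  counts <- table(unlist(lapply(selected_sets, unique)))
  freq <- stats::setNames(as.integer(counts), names(counts))
  if (length(freq)) {
    # deterministic ordering: descending count, then id
    freq <- freq[order(-freq, names(freq))]
  }
  attr(freq, "n_instances") <- length(selected_sets)
  freq
}

#' Call high-frequency risk biomarkers
#'
#' A subpathway is a risk biomarker when it was selected by strictly more
#' than `threshold` classifier instances (default 50, the convention for
#' 150 within-dataset instances).
#'
#' @param freq Named count vector from [feature_frequency()].
#' @param threshold Strict lower bound on the count.
#' @return Character vector of biomarker ids sorted by descending count.
#' @export
call_risk_biomarkers <- function(freq, threshold = 50L) {
  stopifnot(threshold >= 0)
  if (length(freq) == 0L) return(character(0))
  ids <- names(freq)[freq > threshold]
  ids[order(-freq[ids], ids)]
}
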