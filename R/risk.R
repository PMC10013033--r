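#' Per-epoch covariance features on the DNMnet
#'
#' For each corrected epoch, the sample covariance (denominator n-1) over
#' time of the DNMnet channels; the feature vector is the upper triangle
#' including the diagonal in row-major order over node-index-sorted pairs,
#' so m nodes give m(m+1)/2 features.
#'
#' @param corrected a [corrected_epochs()] object.
#' @param net a [dnmnet()] with at least 2 nodes.
#' @return epoch x feature matrix with names `c<i>.c<j>`.
#' @export
epoch_features <- function(corrected, net) {
  m <- length(net$nodes)
  if (m < 2L) stop_invalid("epoch_features: DNMnet needs >= 2 nodes")
  pos <- match(net$nodes, corrected$channel_ids)
  if (anyNA(pos)) stop_invalid("epoch_features: unknown channel id(s)")
  d <- dim(corrected$data)
  ut <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE] # row-major
  feats <- t(vapply(seq_len(d[1]), function(e) {
    cv <- stats::cov(t(corrected$data[e, pos, ]))
    cv[ut]
  }, numeric(nrow(ut))))
  colnames(feats) <- sprintf("c%d.c%d", net$nodes[ut[, 1]], net$nodes[ut[, 2]])
  feats
}

#' Train the epoch-level ensemble classifier
#'
#' Bagged classification trees (majority vote over `n_trees` trees, each
#' grown on a bootstrap resample of the epochs with all features available
#' at every split) separating stable-group epochs (label 1) from
#' near-critical-group epochs (label 0). Reports the resubstitution
#' training accuracy (1 - loss) and a subject-grouped k-fold
#' cross-validation accuracy: all epochs of a subject fall in the same
#' fold, so no subject leaks between training and test.
#'
#' @param features epoch x feature matrix.
#' @param labels 0/1 epoch labels (1 = stable/patient class).
#' @param subject_ids subject identifier per epoch (for fold grouping).
#' @param n_trees number of bagged trees (default 100).
#' @param cv_folds number of folds (default 5); subjects are assigned to
#'   folds stratified by their label.
#' @param seed integer seed.
#' @return object of class `dnm_ensemble`: list with `model`,
#'   `training_accuracy`, `cv_accuracy`, `folds` (subject -> fold map).
#' @export
train_ensemble <- function(features, labels, subject_ids,
                           n_trees = 100, cv_folds = 5, seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_invalid("train_ensemble: both classes must be present")
  if (nrow(features) != length(labels) ||
      length(labels) != length(subject_ids))
    stop_invalid("train_ensemble: features, labels and subject_ids must align")
  set.seed(seed)
  fit_bag <- function(x, y) {
    randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)),
      ntree = n_trees, mtry = ncol(x), replace = TRUE)
  }
  model <- fit_bag(features, labels)
  train_pred <- as.integer(as.character(stats::predict(model, features)))
  training_accuracy <- mean(train_pred == labels)

  # subject-grouped CV, folds stratified by subject label
  subj <- unique(subject_ids)
  subj_lab <- labels[match(subj, subject_ids)]
  folds <- integer(length(subj))
  for (lv in unique(subj_lab)) {
    sel <- which(subj_lab == lv)
    folds[sel] <- rep_len(sample(cv_folds), length(sel))
  }
  names(folds) <- subj
  cv_pred <- rep(NA_integer_, length(labels))
  for (f in seq_len(cv_folds)) {
    test_subj <- subj[folds == f]
    test_idx <- subject_ids %in% test_subj
    if (!any(test_idx) || length(unique(labels[!test_idx])) < 2L) next
    m_f <- fit_bag(features[!test_idx, , drop = FALSE], labels[!test_idx])
    cv_pred[test_idx] <- as.integer(as.character(
      stats::predict(m_f, features[test_idx, , drop = FALSE])))
  }
  cv_accuracy <- mean(cv_pred == labels, na.rm = TRUE)
  structure(list(model = model, training_accuracy = training_accuracy,
                 cv_accuracy = cv_accuracy, folds = folds,
                 n_trees = n_trees, cv_folds = cv_folds),
            class = "dnm_ensemble")
}

#' Subject-level risk
#'
#' The risk of subject k is the mean hard classification output over that
#' subject's epochs: `R_k = (1/n_k) sum_i O_i` with `O_i` the predicted
#' 0/1 label of epoch i, so `R_k` lies in [0, 1].
#'
#' @param ensemble a [train_ensemble()] result (or any object whose `model`
#'   predicts 0/1 factors).
#' @param features epoch x feature matrix for the subjects to score.
#' @param subject_ids subject identifier per epoch.
#' @return named numeric vector of risks in [0, 1], one per subject (in
#'   first-appearance order).
#' @export
subject_risk <- function(ensemble, features, subject_ids) {
  model <- if (inherits(ensemble, "dnm_ensemble")) ensemble$model else ensemble
  o <- as.integer(as.character(stats::predict(model, features)))
  risks <- tapply(o, factor(subject_ids, levels = unique(subject_ids)), mean)
  out <- as.numeric(risks)
  names(out) <- names(risks)
  out
}

#' Cohort risk-accuracy indices
#'
#' Sort the subject risks ascending (ties broken by a stable sort on the
#' subject order). With group sizes n_HC, n_UHR, n_PD, the HC accuracy is
#' the fraction of HC subjects among the n_HC smallest risks, the UHR
#' accuracy the fraction of UHR among the middle n_UHR, the PD accuracy the
#' fraction of PD among the n_PD largest, and the disease accuracy the
#' fraction of UHR or PD among the n_UHR + n_PD largest.
#'
#' @param risks named numeric vector of subject risks.
#' @param groups group label per subject (HC/UHR/PD), aligned with `risks`.
#' @return named numeric vector `c(HC=, UHR=, PD=, disease=)`.
#' @export
risk_accuracy <- function(risks, groups) {
  if (length(risks) != length(groups))
    stop_invalid("risk_accuracy: risks and groups must align")
  for (g in c("HC", "UHR", "PD"))
    if (!any(groups == g)) stop_invalid("risk_accuracy: group '%s' missing", g)
  ord <- order(risks) # stable: ties keep subject order
  g_sorted <- groups[ord]
  n_hc <- sum(groups == "HC"); n_uhr <- sum(groups == "UHR")
  n_pd <- sum(groups == "PD"); N <- length(risks)
  c(HC = mean(g_sorted[seq_len(n_hc)] == "HC"),
    UHR = mean(g_sorted[n_hc + seq_len(n_uhr)] == "UHR"),
    PD = mean(g_sorted[N - n_pd + seq_len(n_pd)] == "PD"),
    disease = mean(g_sorted[N - n_uhr - n_pd + seq_len(n_uhr + n_pd)] %in%
                     c("UHR", "PD")))
}

#' End-to-end risk analysis of a study
#'
#' Builds DNMnet covariance features per epoch, trains the bagged-tree
#' ensemble on the stable (PD, label 1) and near-critical (HC, label 0)
#' epochs only, scores every subject (UHR epochs are never used in
#' training), and computes the cohort risk-accuracy indices when all three
#' groups are present.
#'
#' @param corrected list of [corrected_epochs()] objects.
#' @param net a [dnmnet()] with >= 2 nodes.
#' @param n_trees,cv_folds,seed passed to [train_ensemble()].
#' @return object of class `risk_result`: `risks`, `groups`,
#'   `training_accuracy`, `cv_accuracy`, `risk_accuracy` (or NULL),
#'   `ensemble`.
#' @export
risk_analysis <- function(corrected, net, n_trees = 100, cv_folds = 5,
                          seed = 1) {
  glab <- study_groups(corrected)
  feats <- lapply(corrected, function(ce) epoch_features(ce, net))
  sid <- rep(vapply(corrected, function(ce) ce$subject_id, character(1)),
             vapply(feats, nrow, integer(1)))
  all_feats <- do.call(rbind, feats)
  grp_by_epoch <- rep(glab, vapply(feats, nrow, integer(1)))
  train_idx <- grp_by_epoch %in% c("HC", "PD")
  ens <- train_ensemble(all_feats[train_idx, , drop = FALSE],
                        as.integer(grp_by_epoch[train_idx] == "PD"),
                        sid[train_idx], n_trees, cv_folds, seed)
  risks <- subject_risk(ens, all_feats, sid)
  risks <- risks[vapply(corrected, function(ce) ce$subject_id, character(1))]
  acc <- if (all(c("HC", "UHR", "PD") %in% glab))
    risk_accuracy(risks, glab) else NULL
  structure(list(risks = risks, groups = glab,
                 training_accuracy = ens$training_accuracy,
                 cv_accuracy = ens$cv_accuracy,
                 risk_accuracy = acc, ensemble = ens),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  med <- tapply(x$risks, x$groups, stats::median)
  cat(sprintf("risk analysis: training accuracy %.3f, subject-grouped CV accuracy %.3f\n",
              x$training_accuracy, x$cv_accuracy))
  cat("  median risk by group:",
      paste(sprintf("%s=%.3f", names(med), med), collapse = ", "), "\n")
  if (!is.null(x$risk_accuracy))
    cat("  risk accuracy:",
        paste(sprintf("%s=%.3f", names(x$risk_accuracy), x$risk_accuracy),
              collapse = ", "), "\n")
  invisible(x)
}
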