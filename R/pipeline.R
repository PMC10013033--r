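#' Fit the full dynamical-network-marker criticality analysis
#'
#' The package's central fitting function. From a cohort of oddball
#' recordings (or already-extracted epoch sets) it runs: epoch extraction
#' with baseline correction and amplitude-based artifact rejection,
#' corrected-epoch construction (deviant minus mean standard response), MMN
#' measurement with per-channel group contrasts, DNMnet selection
#' (fluctuation nodes, correlation edges, decreasing-correlation screen),
#' per-subject criticality metrics (DNM index, distribution and network
#' entropy of lagged Gaussian MI, conditional transfer entropy), the three
#' group contrasts per metric, and the epoch-ensemble risk analysis.
#'
#' @param study list of `oddball_recording` or [epoch_set()] objects with
#'   group labels (e.g. from [generate_study()]).
#' @param preprocess a [preprocess_config()].
#' @param delta_t MI/CTE lag in ms (default 20).
#' @param node_alpha,edge_alpha,screen_alpha DNMnet selection levels
#'   (defaults 1e-3, 0.005, 0.05 on BH-adjusted p).
#' @param node_test node-selection test, see [select_nodes()].
#' @param deviant_kind `"dD"` or `"fD"` (MMN amplitude window).
#' @param compute_cte compute the per-subject CTE matrices (default TRUE).
#' @param n_trees,cv_folds,seed risk-ensemble settings.
#' @param groups contrast pair for DNMnet selection (default HC vs PD).
#' @return an object of class `dnm_analysis` with components `dnmnet`,
#'   `metrics` (per-subject data frame), `cte` (list of matrices),
#'   `contrasts` (rank-sum contrast table per metric), `mmn` (amplitude
#'   matrix + channel tests), `risk` (a `risk_result`), `settings`.
#' @seealso [print.dnm_analysis()], [summary.dnm_analysis()],
#'   [plot.dnm_analysis()]
#' @export
dnm_analysis <- function(study, preprocess = preprocess_config(),
                         delta_t = 20, node_alpha = 1e-3,
                         edge_alpha = 0.005, screen_alpha = 0.05,
                         node_test = c("rank_sum", "paired_t"),
                         deviant_kind = c("dD", "fD"), compute_cte = TRUE,
                         n_trees = 100, cv_folds = 5, seed = 1,
                         groups = c("HC", "PD")) {
  node_test <- match.arg(node_test)
  deviant_kind <- match.arg(deviant_kind)
  if (length(study) == 0L) stop_invalid("dnm_analysis: empty study")
  if (inherits(study[[1]], "oddball_recording")) {
    pp <- preprocess_study(study, preprocess)
  } else if (inherits(study[[1]], "epoch_set")) {
    pp <- list(epoch_sets = study, corrected = lapply(study, correct_epochs))
  } else if (inherits(study[[1]], "corrected_epochs")) {
    pp <- list(epoch_sets = NULL, corrected = study)
  } else {
    stop_invalid("dnm_analysis: study must contain oddball_recording, epoch_set or corrected_epochs objects")
  }
  corrected <- pp$corrected
  glab <- study_groups(corrected)
  sids <- vapply(corrected, function(x) x$subject_id, character(1))

  # MMN stage
  mmn_res <- lapply(corrected, mmn_result, deviant_kind = deviant_kind)
  amp <- t(vapply(mmn_res, function(m) m$amplitude,
                  numeric(dim(corrected[[1]]$data)[2])))
  rownames(amp) <- sids
  mmn_tests <- tryCatch(mmn_group_test(amp, glab), error = function(e) NULL)

  # DNMnet selection stage (paired_t needs standard epochs, i.e. epoch sets)
  net_input <- if (is.null(pp$epoch_sets)) corrected else pp$epoch_sets
  net <- build_dnmnet(net_input, node_alpha, edge_alpha, screen_alpha,
                      node_test, groups = groups)

  # criticality metrics stage (an empty DNMnet yields NA metrics but the
  # channel-level CTE is still defined)
  if (length(net$nodes) == 0L)
    warning("dnm_analysis: empty DNMnet at these thresholds; ",
            "DNM index and entropies are NA")
  mets <- lapply(corrected, function(ce) {
    if (length(net$nodes) >= 1L)
      criticality_metrics(ce, net, delta_t, compute_cte)
    else list(dnm_index = NA_real_, distribution_entropy = NA_real_,
              network_entropy = NA_real_,
              cte_matrix = if (compute_cte)
                conditional_transfer_entropy(ce, delta_t) else NULL)
  })
  metrics <- data.frame(
    subject_id = sids, group = glab,
    dnm_index = vapply(mets, `[[`, numeric(1), "dnm_index"),
    distribution_entropy = vapply(mets, `[[`, numeric(1),
                                  "distribution_entropy"),
    network_entropy = vapply(mets, `[[`, numeric(1), "network_entropy"),
    stringsAsFactors = FALSE, row.names = NULL)
  cte <- if (compute_cte) lapply(mets, `[[`, "cte_matrix") else NULL
  if (compute_cte)
    metrics$mean_cte <- vapply(cte, function(m)
      mean(m[row(m) != col(m)]), numeric(1))

  contrasts <- do.call(rbind, lapply(
    c("dnm_index", "distribution_entropy", "network_entropy",
      if (compute_cte) "mean_cte"),
    function(mname) {
      if (all(is.na(metrics[[mname]]))) return(NULL)
      cbind(metric = mname, group_compare(metrics[[mname]], glab))
    }))

  # risk stage (needs >= 2 DNMnet nodes and both training groups)
  risk <- if (length(net$nodes) >= 2L && all(groups %in% glab)) {
    risk_analysis(corrected, net, n_trees, cv_folds, seed)
  } else NULL

  structure(list(dnmnet = net, metrics = metrics, cte = cte,
                 contrasts = contrasts,
                 mmn = list(amplitudes = amp, tests = mmn_tests,
                            results = mmn_res),
                 risk = risk,
                 settings = list(delta_t = delta_t, node_alpha = node_alpha,
                                 edge_alpha = edge_alpha,
                                 screen_alpha = screen_alpha,
                                 node_test = node_test,
                                 deviant_kind = deviant_kind,
                                 n_trees = n_trees, cv_folds = cv_folds,
                                 seed = seed, groups = groups)),
            class = "dnm_analysis")
}

#' @export
print.dnm_analysis <- function(x, ...) {
  cat("Dynamical-network-marker criticality analysis\n")
  cat(sprintf("  subjects: %d (%s)\n", nrow(x$metrics),
              paste(sprintf("%s=%d", names(table(x$metrics$group)),
                            table(x$metrics$group)), collapse = ", ")))
  print(x$dnmnet)
  med <- stats::aggregate(x$metrics[c("dnm_index", "distribution_entropy",
                                      "network_entropy")],
                          by = list(group = x$metrics$group), stats::median)
  cat("  median metrics by group:\n")
  print(med, row.names = FALSE)
  if (!is.null(x$risk)) print(x$risk)
  invisible(x)
}

#' @export
summary.dnm_analysis <- function(object, ...) {
  cat("== DNM criticality analysis summary ==\n\n")
  print(object)
  if (!is.null(object$contrasts)) {
    cat("\n  group contrasts (Wilcoxon rank-sum):\n")
    print(object$contrasts, row.names = FALSE)
  }
  if (!is.null(object$mmn$tests)) {
    sig <- object$mmn$tests[object$mmn$tests$p_adj < 0.05, , drop = FALSE]
    cat(sprintf("\n  MMN: %d significant channel contrasts (adjusted p < 0.05)\n",
                nrow(sig)))
  }
  invisible(object)
}

#' Plot method: metric distributions by group
#'
#' Strip-plus-box panels of the DNM index, distribution entropy, network
#' entropy and (when available) subject risk, by group.
#'
#' @param x a `dnm_analysis` object.
#' @param ... ignored.
#' @export
plot.dnm_analysis <- function(x, ...) {
  mets <- list(`DNM index` = x$metrics$dnm_index,
               `Distribution entropy` = x$metrics$distribution_entropy,
               `Network entropy` = x$metrics$network_entropy)
  if (!is.null(x$risk)) mets$`Risk` <- unname(x$risk$risks)
  grp <- factor(x$metrics$group, levels = intersect(c("HC", "UHR", "PD"),
                                                    unique(x$metrics$group)))
  old <- graphics::par(mfrow = c(2, 2), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(mets)) {
    v <- mets[[nm]]
    graphics::boxplot(v ~ grp, main = nm, xlab = "", ylab = nm,
                      outline = FALSE, border = "grey40",
                      ylim = range(v, na.rm = TRUE))
    graphics::stripchart(v ~ grp, vertical = TRUE, method = "jitter",
                         add = TRUE, pch = 19, cex = 0.6,
                         col = grDevices::adjustcolor("steelblue", 0.7))
  }
  invisible(x)
}

#' Run the pipeline and write result artifacts
#'
#' Orchestrates simulate (optional) -> preprocess -> MMN -> DNMnet ->
#' metrics -> risk and writes `metrics.csv`, `dnmnet.json`, `risks.csv`,
#' `contrasts.csv`, `mmn_tests.csv`, per-group mean CTE matrices and a run
#' log into `out_dir`.
#'
#' @param study list of recordings/epoch sets, or `NULL` to simulate from
#'   `sim` (a [sim_config()]).
#' @param out_dir output directory.
#' @param sim optional [sim_config()] used when `study` is NULL.
#' @param ... passed to [dnm_analysis()].
#' @return the `dnm_analysis` object, invisibly.
#' @export
run_pipeline <- function(study = NULL, out_dir, sim = NULL, ...) {
  if (is.null(study)) {
    if (is.null(sim)) stop_invalid("run_pipeline: provide a study or a sim config")
    study <- generate_study(sim)
  }
  fit <- dnm_analysis(study, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  write_dnmnet(fit$dnmnet, file.path(out_dir, "dnmnet.json"))
  if (!is.null(fit$contrasts))
    utils::write.csv(fit$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
  if (!is.null(fit$mmn$tests))
    utils::write.csv(fit$mmn$tests, file.path(out_dir, "mmn_tests.csv"),
                     row.names = FALSE)
  if (!is.null(fit$risk))
    utils::write.csv(
      data.frame(subject_id = names(fit$risk$risks),
                 group = fit$risk$groups, risk = unname(fit$risk$risks)),
      file.path(out_dir, "risks.csv"), row.names = FALSE)
  if (!is.null(fit$cte)) {
    for (g in unique(fit$metrics$group)) {
      gm <- group_mean_cte(fit$cte, fit$metrics$group, g)
      utils::write.csv(gm$mean,
                       file.path(out_dir, sprintf("mean_cte_%s.csv", g)),
                       row.names = FALSE)
    }
  }
  writeLines(c(sprintf("dnmcrit run %s", format(Sys.time())),
               sprintf("subjects: %d", nrow(fit$metrics)),
               sprintf("settings: %s",
                       paste(names(fit$settings),
                             vapply(fit$settings, function(s)
                               paste(format(s), collapse = "/"), character(1)),
                             sep = "=", collapse = ", "))),
             file.path(out_dir, "run_log.txt"))
  invisible(fit)
}
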