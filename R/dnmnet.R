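# Pool corrected epochs into a (epochs*time) x channel matrix. Per-epoch,
# per-channel demeaning before concatenation removes the stimulus-locked
# (ERP) component so correlations reflect ongoing fluctuation, not the
# shared evoked waveform; switchable.
pool_epochs <- function(corrected, demean_epochs = TRUE) {
  d <- dim(corrected$data)
  # E x C x T -> (T, E) stacked rows per channel
  x <- aperm(corrected$data, c(3, 1, 2)) # T x E x C
  if (demean_epochs) {
    mu <- colMeans(x) # E x C per-epoch channel means
    x <- sweep(x, c(2, 3), mu, "-")
  }
  dim(x) <- c(d[3] * d[1], d[2])
  x
}

#' Per-channel fluctuation of corrected epochs
#'
#' Sample standard deviation (denominator n-1) over all epochs and time
#' samples, per channel — the node-level marker of critical slowing down.
#'
#' @param corrected a [corrected_epochs()] object.
#' @return named numeric vector of SDs (uV) per channel.
#' @export
node_fluctuation <- function(corrected) {
  x <- pool_epochs(corrected, demean_epochs = FALSE)
  if (nrow(x) < 2L) stop_invalid("node_fluctuation: need >= 2 samples")
  stats::setNames(apply(x, 2, stats::sd), corrected$channel_ids)
}

#' Absolute pairwise correlations of corrected epochs
#'
#' Pearson correlation over pooled within-epoch samples (epochs concatenated
#' after per-epoch demeaning), absolute value. A zero-variance channel makes
#' the correlation undefined; it is recorded as 0 with a warning.
#'
#' @param corrected a [corrected_epochs()] object.
#' @param pairs optional 2-column matrix of channel-index pairs; if `NULL`
#'   the full channel x channel matrix of |rho| is returned.
#' @param demean_epochs remove each epoch's per-channel mean before pooling
#'   (default TRUE).
#' @return numeric vector of |rho| per pair, or the full symmetric matrix.
#' @export
edge_correlation <- function(corrected, pairs = NULL, demean_epochs = TRUE) {
  x <- pool_epochs(corrected, demean_epochs)
  if (nrow(x) < 3L) stop_invalid("edge_correlation: need >= 3 paired samples")
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    warning(sprintf("edge_correlation: %d zero-variance channel(s); correlations set to 0",
                    sum(zero)))
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[zero, ] <- 0
  cm[, zero] <- 0
  diag(cm) <- 1
  if (is.null(pairs)) return(cm)
  cm[cbind(pairs[, 1], pairs[, 2])]
}

# Resolve a study argument into corrected epochs + (optionally) epoch sets.
resolve_study <- function(study) {
  if (length(study) == 0L) stop_invalid("empty study")
  first <- study[[1]]
  if (inherits(first, "epoch_set")) {
    list(epoch_sets = study, corrected = lapply(study, correct_epochs))
  } else if (inherits(first, "corrected_epochs")) {
    list(epoch_sets = NULL, corrected = study)
  } else {
    stop_invalid("study must be a list of epoch_set or corrected_epochs objects")
  }
}

study_groups <- function(corrected) {
  vapply(corrected, function(x) x$group, character(1))
}

#' Select DNM nodes
#'
#' Channels whose corrected-epoch fluctuation is significantly elevated in
#' the near-critical group relative to the stable group. Default test:
#' one-sided Wilcoxon rank-sum on per-subject SDs (`groups[1] > groups[2]`),
#' Benjamini-Hochberg adjusted across channels, selected at adjusted
#' p < `alpha`. The `"paired_t"` option instead pairs each near-critical
#' subject's corrected-epoch SD against the same subject's standard-epoch SD
#' (one-sided, corrected > standard), which requires `epoch_set` input.
#'
#' @param study list of [epoch_set()] or [corrected_epochs()] objects with
#'   group labels.
#' @param test `"rank_sum"` (default) or `"paired_t"`.
#' @param alpha significance level on the adjusted p (default 1e-3).
#' @param groups two group labels, contrasted as `groups[1] > groups[2]`.
#' @return list with `nodes` (selected channel indices) and `stats` (data
#'   frame: channel, p, p_adj, and per-group mean SDs).
#' @export
select_nodes <- function(study, test = c("rank_sum", "paired_t"),
                         alpha = 1e-3, groups = c("HC", "PD")) {
  test <- match.arg(test)
  st <- resolve_study(study)
  glab <- study_groups(st$corrected)
  sds <- t(vapply(st$corrected, node_fluctuation,
                  numeric(dim(st$corrected[[1]]$data)[2]))) # subject x channel
  n_ch <- ncol(sds)
  if (test == "rank_sum") {
    i1 <- glab == groups[1]; i2 <- glab == groups[2]
    if (sum(i1) < 2L || sum(i2) < 2L)
      stop_invalid("select_nodes: need >= 2 subjects in each of '%s' and '%s'",
                   groups[1], groups[2])
    p <- vapply(seq_len(n_ch), function(ch)
      rank_sum_test(sds[i1, ch], sds[i2, ch], "greater")$p_value, numeric(1))
  } else {
    if (is.null(st$epoch_sets))
      stop_invalid("select_nodes: paired_t needs epoch_set input (standard epochs)")
    i1 <- glab == groups[1]
    if (sum(i1) < 2L)
      stop_invalid("select_nodes: need >= 2 subjects in '%s'", groups[1])
    std_sds <- t(vapply(st$epoch_sets[i1], function(es) {
      d <- dim(es$standard)
      x <- aperm(es$standard, c(3, 1, 2))
      dim(x) <- c(d[3] * d[1], d[2])
      apply(x, 2, stats::sd)
    }, numeric(n_ch)))
    p <- vapply(seq_len(n_ch), function(ch)
      paired_t_test(sds[i1, ch], std_sds[, ch], "greater")$p_value, numeric(1))
  }
  p_adj <- fdr_adjust(p)
  stats_df <- data.frame(channel = seq_len(n_ch), p = p, p_adj = p_adj)
  stats_df[[paste0("mean_sd_", groups[1])]] <-
    colMeans(sds[glab == groups[1], , drop = FALSE])
  if (any(glab == groups[2]))
    stats_df[[paste0("mean_sd_", groups[2])]] <-
      colMeans(sds[glab == groups[2], , drop = FALSE])
  list(nodes = which(p_adj < alpha), stats = stats_df, test = test,
       alpha = alpha)
}

#' Select DNM edges
#'
#' Channel pairs whose absolute pooled correlation is significantly stronger
#' in the near-critical group (one-sided rank-sum, BH-FDR across pairs,
#' adjusted p < `alpha`). A reverse-direction screen reports pairs whose
#' correlation significantly *decreases* (adjusted p < `screen_alpha`).
#'
#' @inheritParams select_nodes
#' @param alpha edge significance level on the adjusted p (default 0.005).
#' @param screen_alpha level of the decreasing-correlation screen
#'   (default 0.05).
#' @param candidates optional channel indices restricting the pair universe
#'   (default all channels).
#' @param demean_epochs passed to [edge_correlation()].
#' @return list with `edges` (2-column matrix), `stats` (per-pair data
#'   frame), `decreasing` (flagged reverse-direction pairs).
#' @export
select_edges <- function(study, alpha = 0.005, screen_alpha = 0.05,
                         candidates = NULL, groups = c("HC", "PD"),
                         demean_epochs = TRUE) {
  st <- resolve_study(study)
  glab <- study_groups(st$corrected)
  i1 <- glab == groups[1]; i2 <- glab == groups[2]
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop_invalid("select_edges: need >= 2 subjects in each of '%s' and '%s'",
                 groups[1], groups[2])
  n_ch <- dim(st$corrected[[1]]$data)[2]
  if (is.null(candidates)) candidates <- seq_len(n_ch)
  pairs <- t(utils::combn(sort(candidates), 2))
  rho <- t(vapply(st$corrected, function(ce)
    edge_correlation(ce, pairs, demean_epochs), numeric(nrow(pairs))))
  p_inc <- vapply(seq_len(nrow(pairs)), function(k)
    rank_sum_test(rho[i1, k], rho[i2, k], "greater")$p_value, numeric(1))
  p_dec <- vapply(seq_len(nrow(pairs)), function(k)
    rank_sum_test(rho[i1, k], rho[i2, k], "less")$p_value, numeric(1))
  adj_inc <- fdr_adjust(p_inc)
  adj_dec <- fdr_adjust(p_dec)
  stats_df <- data.frame(from = pairs[, 1], to = pairs[, 2],
                         p = p_inc, p_adj = adj_inc,
                         p_decreasing = p_dec, p_adj_decreasing = adj_dec)
  list(edges = pairs[adj_inc < alpha, , drop = FALSE],
       stats = stats_df,
       decreasing = pairs[adj_dec < screen_alpha, , drop = FALSE],
       alpha = alpha, screen_alpha = screen_alpha)
}

#' Construct the DNM subnetwork
#'
#' Composition of [select_nodes()] and [select_edges()]: the leading
#' subnetwork whose members fluctuate significantly more, and whose edges
#' correlate significantly more strongly, in the near-critical group than in
#' the stable group.
#'
#' @inheritParams select_nodes
#' @param node_alpha,edge_alpha,screen_alpha significance levels (defaults
#'   1e-3, 0.005, 0.05 on BH-adjusted p).
#' @param node_test node-selection test, see [select_nodes()].
#' @param edge_universe `"all"` (default: all channel pairs) or `"nodes"`
#'   (pairs among selected nodes only).
#' @return an object of class `dnmnet`: `nodes`, `edges`, `node_stats`,
#'   `edge_stats`, `decreasing_edges`, `direction_checked`, `params`.
#' @export
build_dnmnet <- function(study, node_alpha = 1e-3, edge_alpha = 0.005,
                         screen_alpha = 0.05,
                         node_test = c("rank_sum", "paired_t"),
                         edge_universe = c("all", "nodes"),
                         groups = c("HC", "PD")) {
  node_test <- match.arg(node_test)
  edge_universe <- match.arg(edge_universe)
  ns <- select_nodes(study, node_test, node_alpha, groups)
  candidates <- if (edge_universe == "nodes") ns$nodes else NULL
  es <- if (edge_universe == "nodes" && length(ns$nodes) < 2L) {
    list(edges = matrix(integer(0), 0, 2), stats = NULL,
         decreasing = matrix(integer(0), 0, 2))
  } else {
    select_edges(study, edge_alpha, screen_alpha, candidates, groups)
  }
  dnmnet(ns$nodes, es$edges, node_stats = ns$stats, edge_stats = es$stats,
         decreasing_edges = es$decreasing,
         params = list(node_alpha = node_alpha, edge_alpha = edge_alpha,
                       screen_alpha = screen_alpha, node_test = node_test,
                       edge_universe = edge_universe, groups = groups))
}

#' DNMnet container
#'
#' @param nodes integer channel indices.
#' @param edges 2-column matrix of unordered channel pairs (need not be
#'   incident to selected nodes: nodes and edges are selected by separate
#'   criteria).
#' @param node_stats,edge_stats,decreasing_edges,params optional selection
#'   metadata.
#' @return an object of class `dnmnet`.
#' @export
dnmnet <- function(nodes, edges = matrix(integer(0), 0, 2),
                   node_stats = NULL, edge_stats = NULL,
                   decreasing_edges = NULL, params = NULL) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  structure(list(nodes = as.integer(sort(nodes)), edges = edges,
                 node_stats = node_stats, edge_stats = edge_stats,
                 decreasing_edges = decreasing_edges,
                 direction_checked = !is.null(decreasing_edges),
                 params = params),
            class = "dnmnet")
}

#' @export
print.dnmnet <- function(x, ...) {
  cat(sprintf("DNMnet: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (length(x$nodes)) cat("  nodes:", paste(x$nodes, collapse = " "), "\n")
  if (nrow(x$edges))
    cat("  edges:", paste(apply(x$edges, 1, paste, collapse = "-"),
                          collapse = " "), "\n")
  if (x$direction_checked)
    cat(sprintf("  decreasing-correlation screen: %d pair(s) flagged\n",
                nrow(x$decreasing_edges)))
  invisible(x)
}

#' Serialise / restore a DNMnet as JSON
#'
#' @param net a [dnmnet()] object.
#' @param path file path.
#' @return `read_dnmnet` returns a [dnmnet()] object.
#' @export
write_dnmnet <- function(net, path) {
  jsonlite::write_json(
    list(nodes = net$nodes,
         edges = if (nrow(net$edges)) unclass(as.data.frame(net$edges)) else list(),
         node_stats = net$node_stats, edge_stats = net$edge_stats),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dnmnet
#' @export
read_dnmnet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(x$edges)) cbind(x$edges$V1, x$edges$V2)
           else matrix(integer(0), 0, 2)
  dnmnet(x$nodes, edges,
         node_stats = x$node_stats, edge_stats = x$edge_stats)
}
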