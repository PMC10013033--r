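# Pooled lagged covariance of corrected epochs. Builds, for lag L samples,
# the stacked pairs (x_t, x_{t+L}) within epochs only (lags never cross
# epoch boundaries), per-epoch demeaned by default, and returns the
# (2C x 2C) covariance of cbind(present, lagged) plus the pooled sample
# count. Block [1:C, C+1:2C] holds the lagged cross-covariances.
lagged_aug_cov <- function(corrected, lag_samples, demean_epochs = TRUE) {
  d <- dim(corrected$data)
  E <- d[1]; C <- d[2]; Tn <- d[3]
  if (lag_samples >= Tn)
    stop_invalid("lag (%d samples) must be shorter than the epoch (%d samples)",
                 lag_samples, Tn)
  keep <- Tn - lag_samples
  x <- aperm(corrected$data, c(3, 1, 2)) # T x E x C
  if (demean_epochs) {
    mu <- colMeans(x)
    x <- sweep(x, c(2, 3), mu, "-")
  }
  x0 <- x[seq_len(keep), , , drop = FALSE]
  x1 <- x[lag_samples + seq_len(keep), , , drop = FALSE]
  dim(x0) <- c(keep * E, C)
  dim(x1) <- c(keep * E, C)
  list(S = stats::cov(cbind(x0, x1)), n = keep * E, n_channels = C)
}

clip_rho2 <- function(rho) {
  pmin(rho^2, 1 - 1e-12)
}

#' Gaussian mutual information between two lagged series
#'
#' Under the Gaussian approximation, the lagged mutual information from x to
#' y is `I = -1/2 log(1 - rho^2)` (natural log, nats) with `rho` the Pearson
#' correlation of the pairs `(x_t, y_{t+dt})`. Lagged pairs are formed
#' within rows (epochs) only. The correlation magnitude is clipped so the
#' value stays finite; zero-variance input yields 0 with a warning.
#'
#' @param x,y numeric vectors (one series each) or matrices with one epoch
#'   per row.
#' @param delta_t lag in ms (default 20).
#' @param sampling_rate Hz (default 500).
#' @param demean_epochs for matrix input, demean each epoch first.
#' @return mutual information in nats (>= 0).
#' @export
gaussian_mi <- function(x, y, delta_t = 20, sampling_rate = 500,
                        demean_epochs = TRUE) {
  lag <- as.integer(round(delta_t * sampling_rate / 1000))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (!all(dim(x) == dim(y)))
    stop_invalid("gaussian_mi: x and y must have matching dimensions")
  Tn <- ncol(x)
  if (lag >= Tn) stop_invalid("gaussian_mi: lag (%d samples) >= series length (%d)",
                              lag, Tn)
  if (demean_epochs && nrow(x) > 1L) {
    x <- x - rowMeans(x)
    y <- y - rowMeans(y)
  }
  a <- as.vector(t(x[, seq_len(Tn - lag), drop = FALSE]))
  b <- as.vector(t(y[, lag + seq_len(Tn - lag), drop = FALSE]))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("gaussian_mi: zero-variance input; returning 0")
    return(0)
  }
  rho <- stats::cor(a, b)
  -0.5 * log(1 - clip_rho2(rho))
}

#' Directed lagged mutual-information matrix on DNMnet nodes
#'
#' Gaussian lagged MI for every ordered pair of nodes, from the pooled
#' within-epoch lagged covariance. Diagonal is 0.
#'
#' @param corrected a [corrected_epochs()] object.
#' @param nodes channel indices (default: all channels).
#' @param delta_t lag in ms (default 20).
#' @param demean_epochs demean each epoch before pooling (default TRUE).
#' @return n x n matrix of MI values (nats), rows = source, cols = target.
#' @export
mi_matrix <- function(corrected, nodes = NULL, delta_t = 20,
                      demean_epochs = TRUE) {
  C <- dim(corrected$data)[2]
  if (is.null(nodes)) nodes <- seq_len(C)
  pos <- match(nodes, corrected$channel_ids)
  if (anyNA(pos)) stop_invalid("mi_matrix: unknown channel id(s)")
  lag <- as.integer(round(delta_t * corrected$sampling_rate / 1000))
  lac <- lagged_aug_cov(corrected, lag, demean_epochs)
  S <- lac$S
  v0 <- diag(S)[pos]
  v1 <- diag(S)[C + pos]
  zero <- v0 <= 0 | v1 <= 0
  if (any(zero))
    warning("mi_matrix: zero-variance channel(s); MI set to 0")
  cross <- S[pos, C + pos, drop = FALSE]
  denom <- sqrt(outer(pmax(v0, .Machine$double.eps),
                      pmax(v1, .Machine$double.eps)))
  rho <- cross / denom
  mi <- -0.5 * log(1 - clip_rho2(rho))
  mi[zero, ] <- 0
  mi[, zero] <- 0
  diag(mi) <- 0
  dimnames(mi) <- list(nodes, nodes)
  mi
}

#' DNM index
#'
#' Geometric mean of the DNMnet node standard deviations times the geometric
#' mean of the absolute correlations on the DNMnet edges, computed on
#' corrected epochs. With no edges the edge factor is 1 (empty product); a
#' constant node or zero correlation gives 0, a valid value. The index rises
#' as the system approaches criticality.
#'
#' @param corrected a [corrected_epochs()] object.
#' @param net a [dnmnet()] with at least one node.
#' @param demean_epochs passed to [edge_correlation()].
#' @return non-negative scalar (uV-scaled: multiplying all signals by c > 0
#'   multiplies the index by c).
#' @export
dnm_index <- function(corrected, net, demean_epochs = TRUE) {
  if (length(net$nodes) < 1L) stop_invalid("dnm_index: DNMnet has no nodes")
  pos <- match(net$nodes, corrected$channel_ids)
  if (anyNA(pos)) stop_invalid("dnm_index: unknown channel id(s) in DNMnet")
  sds <- node_fluctuation(corrected)[pos]
  edge_factor <- if (nrow(net$edges) == 0L) 1 else {
    ppos <- cbind(match(net$edges[, 1], corrected$channel_ids),
                  match(net$edges[, 2], corrected$channel_ids))
    geom_mean(edge_correlation(corrected, ppos, demean_epochs))
  }
  geom_mean(sds) * edge_factor
}

#' Distribution entropy of lagged mutual information
#'
#' Normalised Shannon entropy of the directed MI values over the full
#' network between DNMnet nodes: with `N_e = n(n-1)` directed pairs and
#' `p_ij = I_ij / sum(I)`, `Ent_d = -(1 / log N_e) sum p_ij log p_ij`,
#' which lies in [0, 1] and is 1 when information flow is isotropic. If all
#' MI vanish the convention is 1 (maximal uniformity), with a warning.
#' Base-independent by normalisation.
#'
#' @param x a [corrected_epochs()] object, an MI matrix from [mi_matrix()]
#'   (diagonal ignored), or a plain numeric vector of directed MI values.
#' @param nodes,delta_t,demean_epochs used for `corrected_epochs` input.
#' @return scalar in [0, 1].
#' @export
distribution_entropy <- function(x, nodes = NULL, delta_t = 20,
                                 demean_epochs = TRUE) {
  vals <- mi_values(x, nodes, delta_t, demean_epochs, need = 2L)
  norm_entropy(vals) # normalised by log(length(vals))
}

#' Network entropy of outgoing mutual information
#'
#' Per-node normalised outgoing MI `q_ij = I_ij / sum_j I_ij` gives a node
#' entropy `-sum_j q_ij log q_ij`; the network entropy is the mean over
#' nodes (nats), at most `log(n - 1)`. Nodes with no outgoing MI contribute
#' 0, with a warning.
#'
#' @inheritParams distribution_entropy
#' @param x a [corrected_epochs()] object or an MI matrix (n >= 2).
#' @return scalar in [0, log(n-1)] nats.
#' @export
network_entropy <- function(x, nodes = NULL, delta_t = 20,
                            demean_epochs = TRUE) {
  mi <- mi_values(x, nodes, delta_t, demean_epochs, need = 2L,
                  as_matrix = TRUE)
  n <- nrow(mi)
  contrib <- vapply(seq_len(n), function(i) {
    out <- mi[i, -i]
    s <- sum(out)
    if (s == 0) {
      warning("network_entropy: node with all-zero outgoing MI contributes 0")
      return(0)
    }
    q <- out / s
    q <- q[q > 0]
    -sum(q * log(q))
  }, numeric(1))
  mean(contrib)
}

# Shared input handling for the entropy measures.
mi_values <- function(x, nodes, delta_t, demean_epochs, need = 2L,
                      as_matrix = FALSE) {
  if (inherits(x, "corrected_epochs"))
    x <- mi_matrix(x, nodes, delta_t, demean_epochs)
  if (is.matrix(x)) {
    if (nrow(x) < need)
      stop_invalid("entropy measures need >= %d nodes", need)
    if (as_matrix) return(x)
    return(x[row(x) != col(x)])
  }
  if (as_matrix) stop_invalid("network_entropy needs a matrix or corrected_epochs input")
  if (length(x) < 1L) stop_invalid("no MI values supplied")
  x
}

norm_entropy <- function(vals) {
  if (any(vals < 0)) stop_invalid("MI values must be non-negative")
  s <- sum(vals)
  if (s == 0) {
    warning("all mutual information zero; distribution entropy set to 1")
    return(1)
  }
  p <- vals / s
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (length(vals) < 2L) return(0)
  h / log(length(vals))
}

#' Conditional transfer entropy matrix
#'
#' Gaussian conditional transfer entropy for every ordered channel pair:
#' `CTE[x, y] = -1/2 log(1 - r^2)` where `r` is the partial correlation of
#' `(x_t, y_{t+dt})` given all channels at time t except x (including y
#' itself), so indirect influences routed through the present network state
#' are excluded. Computed from the pooled within-epoch lagged covariance via
#' the precision matrix of the 65-variable set (all channels at t plus the
#' lagged target), with a ridge fallback
#' (`lambda = ridge x mean diagonal`) when the covariance is
#' ill-conditioned. Diagonal forced to 0.
#'
#' @param corrected a [corrected_epochs()] object.
#' @param delta_t lag in ms (default 20).
#' @param min_sample_factor required ratio of pooled samples to conditioning
#'   dimension (default 5).
#' @param ridge ridge fraction for the fallback regularisation
#'   (default 1e-6).
#' @param demean_epochs demean each epoch before pooling (default TRUE).
#' @return n x n matrix (nats), rows = source, cols = target, zero diagonal.
#' @export
conditional_transfer_entropy <- function(corrected, delta_t = 20,
                                         min_sample_factor = 5,
                                         ridge = 1e-6,
                                         demean_epochs = TRUE) {
  C <- dim(corrected$data)[2]
  lag <- as.integer(round(delta_t * corrected$sampling_rate / 1000))
  lac <- lagged_aug_cov(corrected, lag, demean_epochs)
  needed <- ceiling(min_sample_factor * (C + 1))
  if (lac$n < needed)
    stop_invalid("conditional_transfer_entropy: %d pooled samples but >= %d required (%gx the %d-variable conditioning set)",
                 lac$n, needed, min_sample_factor, C + 1)
  S <- lac$S
  cte <- matrix(0, C, C)
  for (y in seq_len(C)) {
    idx <- c(seq_len(C), C + y)
    Sig <- S[idx, idx]
    P <- tryCatch({
      if (rcond(Sig) < 1e-12) stop("ill-conditioned")
      solve(Sig)
    }, error = function(e) {
      solve(Sig + diag(ridge * mean(diag(Sig)), nrow(Sig)))
    })
    k <- C + 1L
    r <- -P[seq_len(C), k] / sqrt(pmax(diag(P)[seq_len(C)], .Machine$double.eps) *
                                    max(P[k, k], .Machine$double.eps))
    cte[, y] <- -0.5 * log(1 - clip_rho2(r))
  }
  diag(cte) <- 0
  dimnames(cte) <- list(corrected$channel_ids, corrected$channel_ids)
  cte
}

#' Per-subject criticality metrics
#'
#' Computes the DNM index, distribution entropy, network entropy and
#' (optionally) the full conditional-transfer-entropy matrix for one
#' subject's corrected epochs.
#'
#' @param corrected a [corrected_epochs()] object.
#' @param net a [dnmnet()].
#' @param delta_t lag in ms (default 20).
#' @param compute_cte include the CTE matrix (default TRUE).
#' @param ... passed to [conditional_transfer_entropy()].
#' @return object of class `criticality_metrics`: list with `subject_id`,
#'   `group`, `dnm_index`, `distribution_entropy`, `network_entropy`,
#'   `delta_t`, `mi_matrix` and (optionally) `cte_matrix`.
#' @export
criticality_metrics <- function(corrected, net, delta_t = 20,
                                compute_cte = TRUE, ...) {
  mi <- if (length(net$nodes) >= 2L)
    mi_matrix(corrected, net$nodes, delta_t) else NULL
  res <- list(
    subject_id = corrected$subject_id,
    group = corrected$group,
    dnm_index = dnm_index(corrected, net),
    distribution_entropy = if (!is.null(mi)) distribution_entropy(mi) else NA_real_,
    network_entropy = if (!is.null(mi)) network_entropy(mi) else NA_real_,
    delta_t = delta_t,
    mi_matrix = mi)
  if (compute_cte)
    res$cte_matrix <- conditional_transfer_entropy(corrected, delta_t, ...)
  structure(res, class = "criticality_metrics")
}

#' Group contrasts of a per-subject metric
#'
#' The conventional three contrasts: one-sided rank-sum for "HC > UHR" and
#' "HC > PD", two-sided for "UHR vs PD".
#'
#' @param values named numeric vector of per-subject metric values.
#' @param groups character vector of group labels, aligned with `values`.
#' @return data frame with `contrast`, `alternative`, `p`.
#' @export
group_compare <- function(values, groups) {
  if (length(values) != length(groups))
    stop_invalid("group_compare: values and groups must align")
  spec <- list(list(c("HC", "UHR"), "greater"),
               list(c("HC", "PD"), "greater"),
               list(c("UHR", "PD"), "two.sided"))
  rows <- list()
  for (s in spec) {
    ct <- s[[1]]
    if (!all(ct %in% groups)) next
    p <- rank_sum_test(values[groups == ct[1]], values[groups == ct[2]],
                       s[[2]])$p_value
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste(ct, collapse = if (s[[2]] == "greater") " > " else " vs "),
      alternative = s[[2]], p = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop_invalid("group_compare: no contrastable groups")
  do.call(rbind, rows)
}

#' Group-mean CTE matrix
#'
#' Entrywise mean of per-subject CTE matrices over one group, plus the
#' pooled off-diagonal values (for density summaries).
#'
#' @param cte_list list of n x n CTE matrices.
#' @param groups group label per subject.
#' @param group the group to average.
#' @return list with `mean` (n x n matrix), `values` (pooled off-diagonal
#'   entries), `n_subjects`.
#' @export
group_mean_cte <- function(cte_list, groups, group) {
  sel <- which(groups == group)
  if (length(sel) == 0L) stop_invalid("group_mean_cte: no subjects in group '%s'", group)
  m <- Reduce(`+`, cte_list[sel]) / length(sel)
  vals <- unlist(lapply(cte_list[sel], function(x) x[row(x) != col(x)]))
  list(mean = m, values = vals, n_subjects = length(sel))
}

#' @export
print.criticality_metrics <- function(x, ...) {
  cat(sprintf("criticality metrics '%s' (%s, dt = %g ms): DNMIndex = %.4g, DE = %.4g, NE = %.4g\n",
              x$subject_id, x$group, x$delta_t, x$dnm_index,
              x$distribution_entropy, x$network_entropy))
  if (!is.null(x$cte_matrix))
    cat(sprintf("  mean off-diagonal CTE: %.3g nats\n",
                mean(x$cte_matrix[row(x$cte_matrix) != col(x$cte_matrix)])))
  invisible(x)
}
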