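#' Average ERP over corrected epochs
#'
#' Arithmetic mean over epochs of the corrected (deviant minus mean
#' standard) data: the per-subject MMN difference waveform.
#'
#' @param corrected a [corrected_epochs()] object with at least one epoch.
#' @return channel x time matrix (uV) with attribute `time_axis` (ms).
#' @export
erp_average <- function(corrected) {
  if (dim(corrected$data)[1] < 1L) stop_invalid("erp_average: no epochs")
  w <- apply(corrected$data, c(2, 3), mean)
  attr(w, "time_axis") <- corrected$time_axis
  rownames(w) <- corrected$channel_ids
  w
}

#' MMN peak latency
#'
#' Latency of the most negative sample inside the search window, per
#' channel. Ties are broken to the earliest latency.
#'
#' @param waveform channel x time matrix from [erp_average()] (or any matrix
#'   with a `time_axis` attribute).
#' @param search_window ms pair, default 100-250 ms.
#' @param time_axis optional explicit time axis (ms); defaults to the
#'   waveform attribute.
#' @return named numeric vector of latencies (ms) per channel.
#' @export
mmn_peak_latency <- function(waveform, search_window = c(100, 250),
                             time_axis = attr(waveform, "time_axis")) {
  if (is.null(time_axis)) stop_invalid("mmn_peak_latency: no time axis")
  idx <- which(time_axis >= search_window[1] & time_axis <= search_window[2])
  if (length(idx) == 0L)
    stop_invalid("mmn_peak_latency: search window outside the time axis")
  sub <- waveform[, idx, drop = FALSE]
  # which.min returns the first (earliest) minimum: the tie-break rule
  lat <- time_axis[idx][apply(sub, 1, which.min)]
  stats::setNames(lat, rownames(waveform))
}

#' MMN amplitude (fixed-window mean)
#'
#' Mean signal over a fixed window, per channel: 135-205 ms for the duration
#' deviant (dD) and 100-200 ms for the frequency deviant (fD) by convention.
#'
#' @inheritParams mmn_peak_latency
#' @param window ms pair; if missing, taken from `deviant_kind`.
#' @param deviant_kind `"dD"` (window 135-205 ms) or `"fD"` (100-200 ms).
#' @return named numeric vector of amplitudes (uV) per channel.
#' @export
mmn_amplitude <- function(waveform, window = NULL,
                          deviant_kind = c("dD", "fD"),
                          time_axis = attr(waveform, "time_axis")) {
  if (is.null(window)) {
    deviant_kind <- match.arg(deviant_kind)
    window <- if (deviant_kind == "dD") c(135, 205) else c(100, 200)
  }
  if (is.null(time_axis)) stop_invalid("mmn_amplitude: no time axis")
  idx <- which(time_axis >= window[1] & time_axis <= window[2])
  if (length(idx) == 0L)
    stop_invalid("mmn_amplitude: empty window after grid mapping")
  stats::setNames(rowMeans(waveform[, idx, drop = FALSE]), rownames(waveform))
}

#' Per-subject MMN summary
#'
#' @param corrected a [corrected_epochs()] object.
#' @param deviant_kind `"dD"` or `"fD"` (sets the amplitude window).
#' @return object of class `mmn_result`: list with `waveform`,
#'   `peak_latency`, `amplitude`, `deviant_kind`.
#' @export
mmn_result <- function(corrected, deviant_kind = c("dD", "fD")) {
  deviant_kind <- match.arg(deviant_kind)
  w <- erp_average(corrected)
  structure(list(subject_id = corrected$subject_id, group = corrected$group,
                 waveform = w,
                 peak_latency = mmn_peak_latency(w),
                 amplitude = mmn_amplitude(w, deviant_kind = deviant_kind),
                 deviant_kind = deviant_kind),
            class = "mmn_result")
}

#' Per-channel MMN group contrasts
#'
#' Rank-sum tests of the per-subject MMN amplitudes between groups for each
#' channel, Benjamini-Hochberg adjusted across channels. The three standard
#' contrasts (HC vs PD, HC vs UHR, UHR vs PD) are two-sided.
#'
#' @param amplitudes subject x channel matrix of MMN amplitudes.
#' @param groups character vector of group labels, one per subject.
#' @param contrasts list of 2-element group pairs; defaults to the three
#'   standard contrasts restricted to groups present.
#' @return data frame with columns `contrast`, `channel`, `p`, `p_adj`.
#' @export
mmn_group_test <- function(amplitudes, groups,
                           contrasts = NULL) {
  if (nrow(amplitudes) != length(groups))
    stop_invalid("mmn_group_test: one group label per subject required")
  present <- unique(groups)
  if (is.null(contrasts)) {
    std <- list(c("HC", "PD"), c("HC", "UHR"), c("UHR", "PD"))
    contrasts <- Filter(function(ct) all(ct %in% present), std)
  }
  if (length(contrasts) == 0L)
    stop_invalid("mmn_group_test: no testable contrasts among groups %s",
                 paste(present, collapse = ", "))
  out <- list()
  for (ct in contrasts) {
    if (sum(groups == ct[1]) < 2L || sum(groups == ct[2]) < 2L)
      stop_invalid("mmn_group_test: need >= 2 subjects in '%s' and '%s'",
                   ct[1], ct[2])
    p <- vapply(seq_len(ncol(amplitudes)), function(ch) {
      rank_sum_test(amplitudes[groups == ct[1], ch],
                    amplitudes[groups == ct[2], ch])$p_value
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      contrast = paste(ct, collapse = " vs "),
      channel = seq_len(ncol(amplitudes)),
      p = p, p_adj = fdr_adjust(p), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.mmn_result <- function(x, ...) {
  ch <- which.min(x$amplitude)
  cat(sprintf("MMN (%s) for '%s' (%s): strongest channel %d, amplitude %.2f uV, peak latency %g ms\n",
              x$deviant_kind, x$subject_id, x$group, ch, x$amplitude[ch],
              x$peak_latency[ch]))
  invisible(x)
}
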