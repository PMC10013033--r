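#' Preprocessing configuration
#'
#' @param epoch_window ms pair relative to stimulus onset, inclusive start /
#'   exclusive end (default -100..400, covering the 100-250 ms MMN search
#'   window with a pre-stimulus baseline).
#' @param baseline_window ms pair for per-epoch baseline subtraction
#'   (default -100..0); must lie inside `epoch_window`.
#' @param reject_amplitude absolute peak rejection threshold in uV
#'   (default 100); `Inf` disables rejection.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(epoch_window = c(-100, 400),
                              baseline_window = c(-100, 0),
                              reject_amplitude = 100) {
  if (length(epoch_window) != 2L || epoch_window[1] >= epoch_window[2])
    stop_invalid("epoch_window must be an increasing ms pair")
  if (baseline_window[1] < epoch_window[1] ||
      baseline_window[2] > epoch_window[2])
    stop_invalid("baseline_window must lie inside epoch_window")
  if (!(reject_amplitude > 0))
    stop_invalid("reject_amplitude must be > 0")
  structure(list(epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 reject_amplitude = reject_amplitude),
            class = "preprocess_config")
}

#' Extract baseline-corrected epochs from a recording
#'
#' Cuts one epoch per stimulus event over `config$epoch_window` (times mapped
#' to the sample grid, inclusive start / exclusive end) and subtracts the
#' per-epoch per-channel mean over `config$baseline_window`. Events whose
#' window falls outside the recording are dropped with a message.
#'
#' @param recording an `oddball_recording`.
#' @param config a [preprocess_config()].
#' @return an [epoch_set()].
#' @export
extract_epochs <- function(recording, config = preprocess_config()) {
  fs <- recording$sampling_rate
  w0 <- as.integer(round(config$epoch_window[1] * fs / 1000))
  w1 <- as.integer(round(config$epoch_window[2] * fs / 1000))
  rel <- w0:(w1 - 1L) # inclusive start, exclusive end
  time_axis <- rel * 1000 / fs
  n_samp <- ncol(recording$signal)
  onsets <- recording$events$onset_sample
  ok <- (onsets + rel[1] >= 1L) & (onsets + rel[length(rel)] <= n_samp)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(sprintf("extract_epochs: dropped %d edge event(s)", n_dropped))
  if (!any(ok))
    stop_invalid("extract_epochs: no epochs remain after edge-dropping")
  onsets <- onsets[ok]
  kinds <- recording$events$kind[ok]
  C <- nrow(recording$signal)
  Tn <- length(rel)
  idx <- outer(rel, onsets, "+") # T x E sample indices
  # gather: channel x (T*E) -> E x C x T
  flat <- recording$signal[, as.vector(idx), drop = FALSE]
  arr <- aperm(array(flat, dim = c(C, Tn, length(onsets))), c(3, 1, 2))
  # baseline subtraction
  b_idx <- window_indices(time_axis, config$baseline_window)
  if (length(b_idx) > 0L) {
    bl <- apply(arr[, , b_idx, drop = FALSE], c(1, 2), mean)
    arr <- arr - as.vector(bl) # recycles over the time dimension
  }
  epoch_set(recording$subject_id, recording$group, fs, time_axis,
            standard = arr[kinds == "standard", , , drop = FALSE],
            deviant = arr[kinds == "deviant", , , drop = FALSE])
}

#' Reject high-amplitude epochs
#'
#' Drops any epoch whose absolute value exceeds the threshold on any channel
#' at any sample — a simple, reproducible amplitude-rejection rule standing
#' in for interactive artifact pipelines.
#'
#' @param epochs an [epoch_set()].
#' @param config a [preprocess_config()] (uses `reject_amplitude`).
#' @return the filtered [epoch_set()]; rejection counts per kind are reported
#'   via `message()` when non-zero.
#' @export
reject_artifacts <- function(epochs, config = preprocess_config()) {
  thr <- config$reject_amplitude
  keep_of <- function(a) {
    if (dim(a)[1] == 0L) return(logical(0))
    apply(abs(a) <= thr, 1, all)
  }
  ks <- keep_of(epochs$standard)
  kd <- keep_of(epochs$deviant)
  if (sum(ks) + sum(kd) == 0L)
    stop_invalid("reject_artifacts: all epochs rejected at threshold %g uV", thr)
  n_rej <- c(standard = sum(!ks), deviant = sum(!kd))
  if (any(n_rej > 0))
    message(sprintf("reject_artifacts: rejected %d standard, %d deviant epoch(s)",
                    n_rej[1], n_rej[2]))
  epoch_set(epochs$subject_id, epochs$group, epochs$sampling_rate,
            epochs$time_axis,
            standard = epochs$standard[ks, , , drop = FALSE],
            deviant = epochs$deviant[kd, , , drop = FALSE],
            channel_ids = epochs$channel_ids)
}

#' Build corrected epochs (the empirical difference process)
#'
#' Subtracts the mean standard response, sample by sample, from every deviant
#' epoch: `data[e, c, t] = deviant[e, c, t] - mean_e' standard[e', c, t]`.
#'
#' @param epochs an [epoch_set()] with at least one standard and one deviant
#'   epoch.
#' @return a [corrected_epochs()] object.
#' @export
correct_epochs <- function(epochs) {
  if (dim(epochs$standard)[1] < 1L)
    stop_invalid("correct_epochs: no standard epochs to average")
  if (dim(epochs$deviant)[1] < 1L)
    stop_invalid("correct_epochs: no deviant epochs")
  std_mean <- apply(epochs$standard, c(2, 3), mean) # channel x time
  dat <- epochs$deviant
  dat <- sweep(dat, c(2, 3), std_mean, "-")
  corrected_epochs(epochs$subject_id, epochs$group, epochs$sampling_rate,
                   epochs$time_axis, dat, epochs$channel_ids)
}

#' Preprocess a whole study
#'
#' Convenience wrapper: epoch extraction, artifact rejection and
#' corrected-epoch construction for every recording.
#'
#' @param recordings list of `oddball_recording` objects (e.g. from
#'   [generate_study()]).
#' @param config a [preprocess_config()].
#' @return list with `epoch_sets` and `corrected` (both named by subject).
#' @export
preprocess_study <- function(recordings, config = preprocess_config()) {
  epoch_sets <- lapply(recordings, function(r) {
    reject_artifacts(extract_epochs(r, config), config)
  })
  corrected <- lapply(epoch_sets, correct_epochs)
  list(epoch_sets = epoch_sets, corrected = corrected)
}
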