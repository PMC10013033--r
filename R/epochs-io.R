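#' Epoch set container
#'
#' Per-subject stacks of baseline-corrected epochs split by stimulus kind.
#' Arrays are epoch x channel x time; the time axis is in ms relative to
#' stimulus onset on a uniform grid with step `1000 / sampling_rate`.
#' Channel indices are 1-based, matching the montage numbering.
#'
#' @param subject_id subject identifier.
#' @param group group label.
#' @param sampling_rate Hz.
#' @param time_axis ms grid, strictly increasing.
#' @param standard,deviant epoch x channel x time arrays (uV) sharing the
#'   channel and time dimensions.
#' @param channel_ids 1-based channel indices (default `1:n_channels`).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(subject_id, group, sampling_rate, time_axis,
                      standard, deviant, channel_ids = NULL) {
  if (length(dim(standard)) != 3L || length(dim(deviant)) != 3L)
    stop_invalid("standard and deviant must be epoch x channel x time arrays")
  if (!all(dim(standard)[2:3] == dim(deviant)[2:3]))
    stop_invalid("standard and deviant arrays must share channel and time dimensions")
  if (dim(standard)[3] != length(time_axis))
    stop_invalid("time_axis length does not match the time dimension")
  step <- 1000 / sampling_rate
  if (length(time_axis) > 1L &&
      max(abs(diff(time_axis) - step)) > 1e-6)
    stop_invalid("time_axis must be uniform with step 1000/sampling_rate ms")
  if (is.null(channel_ids)) channel_ids <- seq_len(dim(standard)[2])
  if (anyDuplicated(channel_ids)) stop_invalid("channel_ids must be unique")
  structure(list(subject_id = subject_id, group = group,
                 sampling_rate = sampling_rate, time_axis = time_axis,
                 standard = standard, deviant = deviant,
                 channel_ids = as.integer(channel_ids)),
            class = "epoch_set")
}

#' Corrected-epoch container
#'
#' Deviant epochs with the subject's mean standard response subtracted
#' sample-wise: the empirical difference process z(t).
#'
#' @param subject_id,group,sampling_rate,time_axis,channel_ids as in
#'   [epoch_set()].
#' @param data epoch x channel x time array (uV).
#' @return an object of class `corrected_epochs`.
#' @export
corrected_epochs <- function(subject_id, group, sampling_rate, time_axis,
                             data, channel_ids = NULL) {
  if (length(dim(data)) != 3L)
    stop_invalid("data must be an epoch x channel x time array")
  if (dim(data)[3] != length(time_axis))
    stop_invalid("time_axis length does not match the time dimension")
  if (is.null(channel_ids)) channel_ids <- seq_len(dim(data)[2])
  structure(list(subject_id = subject_id, group = group,
                 sampling_rate = sampling_rate, time_axis = time_axis,
                 data = data, channel_ids = as.integer(channel_ids)),
            class = "corrected_epochs")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch set '%s' (%s): %d standard + %d deviant epochs, %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group, dim(x$standard)[1], dim(x$deviant)[1],
              dim(x$standard)[2], dim(x$standard)[3], x$sampling_rate))
  invisible(x)
}

#' @export
print.corrected_epochs <- function(x, ...) {
  cat(sprintf("corrected epochs '%s' (%s): %d epochs x %d channels x %d samples\n",
              x$subject_id, x$group, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3]))
  invisible(x)
}

#' Write an epoch-set study archive
#'
#' Writes a directory with `manifest.json` (subjects, groups, sampling rate,
#' montage, time axis) and one long-format CSV per subject with columns
#' `epoch, kind, channel, sample, value`. Values are serialised with 17
#' significant digits, so the round trip through [read_study()] is exact for
#' doubles.
#'
#' @param path target directory (created if missing).
#' @param epoch_sets list of [epoch_set()] objects.
#' @return the manifest, invisibly.
#' @export
write_study <- function(path, epoch_sets) {
  if (length(epoch_sets) == 0L) stop_invalid("write_study: empty collection")
  if (inherits(epoch_sets, "epoch_set")) epoch_sets <- list(epoch_sets)
  ids <- vapply(epoch_sets, function(e) e$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_invalid("write_study: duplicate subject_id '%s'",
                 ids[anyDuplicated(ids)])
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  e1 <- epoch_sets[[1]]
  manifest <- list(
    format = "dnmcrit-epochs-csv-v1",
    subjects = ids,
    groups = vapply(epoch_sets, function(e) e$group, character(1)),
    sampling_rate = e1$sampling_rate,
    n_channels = dim(e1$standard)[2],
    channel_ids = e1$channel_ids,
    time_axis = e1$time_axis,
    n_standard = vapply(epoch_sets, function(e) dim(e$standard)[1], numeric(1)),
    n_deviant = vapply(epoch_sets, function(e) dim(e$deviant)[1], numeric(1)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (es in epoch_sets) write_subject_csv(path, es)
  invisible(manifest)
}

write_subject_csv <- function(path, es) {
  rows <- lapply(c("standard", "deviant"), function(kind) {
    a <- es[[kind]]
    d <- dim(a)
    if (prod(d) == 0L) return(NULL)
    data.frame(
      epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
      kind = kind,
      channel = rep(rep(es$channel_ids, each = d[1]), times = d[3]),
      sample = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = sprintf("%.17g", as.vector(a)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(path, paste0(es$subject_id, ".csv")),
                   row.names = FALSE, quote = FALSE)
}

#' Read an epoch-set study archive
#'
#' Inverse of [write_study()]; validates the container invariants (array
#' dimensions against the manifest, uniform time axis, unique channels) on
#' load.
#'
#' @param path archive directory.
#' @return list of [epoch_set()] objects, named by subject.
#' @export
read_study <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_invalid("read_study: no manifest.json in '%s'", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- list()
  for (i in seq_along(manifest$subjects)) {
    sid <- manifest$subjects[i]
    f <- file.path(path, paste0(sid, ".csv"))
    if (!file.exists(f))
      stop_invalid("read_study: missing subject file '%s'", f)
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = c(epoch = "integer", kind = "character",
                                         channel = "integer",
                                         sample = "integer", value = "numeric"))
    arrs <- lapply(c("standard", "deviant"), function(kind) {
      sub <- df[df$kind == kind, , drop = FALSE]
      ne <- if (nrow(sub)) max(sub$epoch) else 0L
      nt <- length(manifest$time_axis)
      nc <- manifest$n_channels
      a <- array(0, dim = c(ne, nc, nt))
      if (nrow(sub)) {
        ch_idx <- match(sub$channel, manifest$channel_ids)
        a[cbind(sub$epoch, ch_idx, sub$sample)] <- sub$value
      }
      a
    })
    expected <- c(manifest$n_standard[i], manifest$n_deviant[i])
    got <- c(dim(arrs[[1]])[1], dim(arrs[[2]])[1])
    if (!all(expected == got))
      stop_invalid("read_study: '%s' has %d/%d epochs but manifest says %d/%d",
                   sid, got[1], got[2], expected[1], expected[2])
    out[[sid]] <- epoch_set(sid, manifest$groups[i], manifest$sampling_rate,
                            manifest$time_axis, arrs[[1]], arrs[[2]],
                            manifest$channel_ids)
  }
  out
}
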